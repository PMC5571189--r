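#' Timing-dependent eligibility waveform
#'
#' Synapse-local memory of a recent pre/post pairing:
#' `e(t) = (t/tau_r)^k * exp(k (1 - t/tau_r))` for `t > 0`, zero before the
#' pairing. The waveform rises to a peak of 1 at `t = tau_r` and decays to
#' below 1% of its peak within about 3 s at the reference parameters, which
#' is the window within which delayed reinforcement can act.
#'
#' @param t time since the pairing (s); vectorized.
#' @param k sharpness exponent.
#' @param tau_r rise scale (s), the peak time.
#' @return eligibility values in `[0, 1]` per pairing.
#' @export
eligibility_waveform <- function(t, k = 12, tau_r = 0.90) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tau_r)^k * exp(k * (1 - t[pos] / tau_r))
  out
}

#' Reinforcement signal kernel
#'
#' Normalized response of two chained leaky integrators to an impulse -- the
#' standard bi-exponential `exp(-t/tau_decay) - exp(-t/tau_rise)`, scaled to
#' peak at 1. Used for both the dopaminergic and the thalamic reinforcement
#' signals. Equal time constants degenerate smoothly to the alpha function
#' `(t/tau) exp(1 - t/tau)`.
#'
#' @param t time since kernel onset (s); vectorized, zero for `t <= 0`.
#' @param tau_rise_s,tau_decay_s rise and decay constants (s).
#' @param amplitude peak value (default 1).
#' @param onset_delay_s shift of the kernel onset (s).
#' @return kernel values, non-negative, peaking at `amplitude`.
#' @export
signal_kernel <- function(t, tau_rise_s, tau_decay_s, amplitude = 1,
                          onset_delay_s = 0) {
  u <- t - onset_delay_s
  out <- numeric(length(u))
  pos <- u > 0
  if (abs(tau_rise_s - tau_decay_s) < 1e-12) {
    out[pos] <- (u[pos] / tau_rise_s) * exp(1 - u[pos] / tau_rise_s)
  } else {
    tr <- min(tau_rise_s, tau_decay_s); td <- max(tau_rise_s, tau_decay_s)
    tp <- kernel_peak_time(tr, td)
    norm <- exp(-tp / td) - exp(-tp / tr)
    out[pos] <- (exp(-u[pos] / td) - exp(-u[pos] / tr)) / norm
  }
  amplitude * out
}

#' Closed-form peak time of the bi-exponential kernel
#'
#' @param tau_rise_s,tau_decay_s rise and decay constants (s).
#' @return `log(tau_decay/tau_rise) / (1/tau_rise - 1/tau_decay)`, or
#'   `tau_rise_s` in the equal-constant alpha limit.
#' @export
kernel_peak_time <- function(tau_rise_s, tau_decay_s) {
  if (abs(tau_rise_s - tau_decay_s) < 1e-12) return(tau_rise_s)
  log(tau_decay_s / tau_rise_s) / (1 / tau_rise_s - 1 / tau_decay_s)
}

#' Analytic integral of the normalized bi-exponential kernel over [0, Inf)
#'
#' @inheritParams kernel_peak_time
#' @return finite integral of [signal_kernel()] with unit amplitude.
#' @export
kernel_integral <- function(tau_rise_s, tau_decay_s) {
  if (abs(tau_rise_s - tau_decay_s) < 1e-12) return(exp(1) * tau_rise_s)
  tr <- min(tau_rise_s, tau_decay_s); td <- max(tau_rise_s, tau_decay_s)
  tp <- kernel_peak_time(tr, td)
  (td - tr) / (exp(-tp / td) - exp(-tp / tr))
}

#' Seed eligibility traces from a pre/post pairing
#'
#' A pre-before-post pairing within the window (`0 < dt <= pairing_window_ms`)
#' seeds a potentiation trace; post-before-pre seeds a depression trace with
#' the same waveform. Pairings outside the window are no-ops. Trace seeds
#' superpose additively: the state stores the pairing times and the traces
#' are evaluated lazily with [eligibility_waveform()].
#'
#' @param state eligibility state from [eligibility_state()], or `NULL`.
#' @param dt_ms pre-to-post interval (ms), positive for pre-before-post.
#' @param t_pairing_s absolute time of the pairing (s).
#' @param rule a [plasticity_rule_params()].
#' @return updated eligibility state.
#' @export
update_eligibility <- function(state = NULL, dt_ms, t_pairing_s = 0,
                               rule = plasticity_rule_params()) {
  if (is.null(state)) state <- eligibility_state()
  if (is.na(dt_ms) || abs(dt_ms) > rule$pairing_window_ms) return(state)
  if (dt_ms > 0) state$pot_seeds <- c(state$pot_seeds, t_pairing_s)
  else if (dt_ms < 0) state$dep_seeds <- c(state$dep_seeds, t_pairing_s)
  state
}

#' Empty eligibility state
#' @return object of class `eligibility_state` with no seeded traces.
#' @export
eligibility_state <- function() {
  structure(list(pot_seeds = numeric(), dep_seeds = numeric()),
            class = "eligibility_state")
}

#' Evaluate the superposed eligibility traces
#'
#' @param state an `eligibility_state`.
#' @param t times (s) at which to evaluate.
#' @param rule a [plasticity_rule_params()].
#' @return list with `e_pot` and `e_dep` trace vectors (dimensionless, >= 0).
#' @export
eligibility_traces <- function(state, t, rule = plasticity_rule_params()) {
  sum_tr <- function(seeds) {
    if (!length(seeds)) return(numeric(length(t)))
    Reduce(`+`, lapply(seeds, function(s)
      eligibility_waveform(t - s, rule$elig_k, rule$elig_tau_r_s)))
  }
  list(e_pot = sum_tr(state$pot_seeds), e_dep = sum_tr(state$dep_seeds))
}

## cache of best-case conjunction integrals, keyed by the rule constants
.ref_cache <- new.env(parent = emptyenv())

## Best-case eligibility-weighted conjunction integral: a single pairing with
## DA and Th delivered together at the optimal common delay. Used to decide
## when a conjunction counts as absent (kappa pathway).
conjunction_reference <- function(rule) {
  key <- paste(rule$elig_k, rule$elig_tau_r_s, rule$da_tau_rise_s,
               rule$da_tau_decay_s, rule$th_tau_rise_s, rule$th_tau_decay_s,
               rule$dt_slow_s, rule$integration_horizon_s, sep = "|")
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  d <- seq(0, 3, by = 0.05)
  I <- vapply(d, function(x) conjunction_integral(rule,
    da_events = data.frame(time_s = x, gain = 1),
    th_events = data.frame(time_s = x, gain = 1)), 0)
  .ref_cache[[key]] <- max(I)
  .ref_cache[[key]]
}

## eligibility-weighted integral of min(DA, Th) for one potentiation trace
## seeded at t = 0; da/th events are data.frames (time_s, gain)
conjunction_integral <- function(rule, da_events, th_events,
                                 seeds = 0) {
  dt <- rule$dt_slow_s
  tt <- seq(dt, rule$integration_horizon_s, by = dt)
  e <- Reduce(`+`, lapply(seeds, function(s)
    eligibility_waveform(tt - s, rule$elig_k, rule$elig_tau_r_s)))
  da <- signal_series(rule, tt, da_events, "da") * rule$da_block_scale
  th <- signal_series(rule, tt, th_events, "th")
  sum(e * pmin(da, th)) * dt
}

signal_series <- function(rule, tt, events, kind = c("da", "th")) {
  kind <- match.arg(kind)
  taus <- if (kind == "da") c(rule$da_tau_rise_s, rule$da_tau_decay_s)
          else c(rule$th_tau_rise_s, rule$th_tau_decay_s)
  if (is.null(events) || !nrow(events)) return(numeric(length(tt)))
  Reduce(`+`, lapply(seq_len(nrow(events)), function(i)
    signal_kernel(tt - events$time_s[i], taus[1], taus[2],
                  amplitude = events$gain[i])))
}

#' Weight change from reinforcement acting on an eligibility trace
#'
#' Implements the three-factor readout for one pairing event. With a
#' potentiation trace seeded at `t = 0`:
#' `dw = a2a_block_scale * eta_pot * I - kappa_baseline * [I ~ 0]`
#' where `I` is the eligibility-weighted integral of the conjunction
#' `min(DA(t), Th(t))` of the reinforcement signals, and the baseline
#' depression `kappa_baseline` applies only when the conjunction is
#' effectively absent (`I` below `conj_zero_frac` of the best-case
#' integral). A depression trace gives `dw = -eta_dep * I` with no baseline
#' term, so unreinforced negative pairings leave the weight unchanged.
#' Dopamine or thalamic input arriving alone, or outside the eligibility
#' window, yields a null or negative change.
#'
#' @param rule a [plasticity_rule_params()].
#' @param pairing_sign `+1` for a potentiation-eligible (pre-before-post)
#'   pairing, `-1` for a depression-eligible one.
#' @param da_events,th_events data.frames (`time_s`, `gain`) of reinforcement
#'   deliveries relative to the pairing; `NULL` for none.
#' @return list with `dw` and the conjunction integral `conj`.
#' @export
apply_reinforcement <- function(rule, pairing_sign, da_events = NULL,
                                th_events = NULL) {
  stopifnot(pairing_sign %in% c(-1, 1))
  I <- conjunction_integral(rule, da_events, th_events)
  if (pairing_sign > 0) {
    ref <- conjunction_reference(rule)
    unreinforced <- I < rule$conj_zero_frac * ref
    dw <- rule$a2a_block_scale * rule$eta_pot * I -
      rule$kappa_baseline * as.numeric(unreinforced)
  } else {
    dw <- -rule$eta_dep * I
  }
  list(dw = dw, conj = I)
}

#' Synaptic weight change as a function of reinforcement timing
#'
#' For a single positive (pre-before-post) pairing at `t = 0`, evaluates the
#' predicted weight change on a grid of dopamine and thalamic delivery
#' delays. The map has a single positive region; along the equal-delay
#' diagonal the half-maximum potentiation interval spans roughly 0.4--1.1 s
#' under the reference parameterization.
#'
#' @param rule a [plasticity_rule_params()].
#' @param t_da,t_th delay grids (s); must lie within the 0--3 s kernel
#'   support window.
#' @return object of class `weight_surface`: `t_da`, `t_th`, and the `dw`
#'   matrix (rows index `t_da`).
#' @export
weight_change_surface <- function(rule = plasticity_rule_params(),
                                  t_da = seq(0, 3, by = 0.025),
                                  t_th = t_da) {
  if (any(t_da < 0 | t_da > 3) || any(t_th < 0 | t_th > 3))
    stop("weight_change_surface: delay grid outside the [0, 3] s support")
  dw <- matrix(NA_real_, length(t_da), length(t_th))
  for (i in seq_along(t_da)) for (j in seq_along(t_th)) {
    dw[i, j] <- apply_reinforcement(rule, +1,
      da_events = data.frame(time_s = t_da[i], gain = 1),
      th_events = data.frame(time_s = t_th[j], gain = 1))$dw
  }
  structure(list(t_da = t_da, t_th = t_th, dw = dw, rule = rule),
            class = "weight_surface")
}

#' Half-maximum potentiation interval along the equal-delay diagonal
#'
#' @param surface a `weight_surface` with identical `t_da`/`t_th` grids.
#' @return list with `lower_s`, `upper_s` (the smallest and largest diagonal
#'   delays at which the weight change is at least half its maximum),
#'   `peak_s`, `max_dw`, and `contiguous`.
#' @export
half_max_interval <- function(surface) {
  stopifnot(inherits(surface, "weight_surface"))
  if (!isTRUE(all.equal(surface$t_da, surface$t_th)))
    stop("half_max_interval: needs matching delay grids")
  d <- surface$t_da
  v <- diag(surface$dw)
  mx <- max(v)
  if (mx <= 0) stop("half_max_interval: no potentiation on the diagonal")
  sel <- which(v >= 0.5 * mx)
  list(lower_s = d[min(sel)], upper_s = d[max(sel)], peak_s = d[which.max(v)],
       max_dw = mx, contiguous = all(diff(sel) == 1))
}

#' @export
print.weight_surface <- function(x, ...) {
  hm <- tryCatch(half_max_interval(x), error = function(e) NULL)
  cat(sprintf("weight_surface: %d x %d delays on [%.2f, %.2f] s\n",
              length(x$t_da), length(x$t_th), min(x$t_da), max(x$t_da)))
  if (!is.null(hm))
    cat(sprintf("  diagonal half-max potentiation: %.3f - %.3f s (peak %.3f s)\n",
                hm$lower_s, hm$upper_s, hm$peak_s))
  invisible(x)
}
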