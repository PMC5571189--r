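#' @keywords internal
new_membrane_recording <- function(vm, sampling_rate_hz, duration_s, events,
                                   meta) {
  stopifnot(sampling_rate_hz > 0, all(is.finite(vm)))
  if (nrow(events) && (any(events$time_s < 0) || any(events$time_s > duration_s)))
    stop("membrane_recording: event times must lie within [0, duration]")
  structure(list(vm = vm, sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s, events = events, meta = meta),
            class = "membrane_recording")
}

#' Time axis of a recording
#'
#' @param rec a `membrane_recording`.
#' @return numeric vector of sample times (s), uniform step `1/sampling_rate_hz`.
#' @export
time_axis <- function(rec) {
  stopifnot(inherits(rec, "membrane_recording"))
  (seq_along(rec$vm) - 1) / rec$sampling_rate_hz
}

#' @export
print.membrane_recording <- function(x, ...) {
  cat(sprintf("membrane_recording: %.1f s at %g Hz (%d samples), %d events\n",
              x$duration_s, x$sampling_rate_hz, length(x$vm), nrow(x$events)))
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}

## Draw one dwell time; gamma-distributed with the requested CV, degenerate at
## the mean when cv = 0. A floor keeps dwells longer than the transition ramp.
draw_dwell <- function(mean_s, cv, floor_s = 0.05) {
  d <- if (cv <= 0) mean_s else
    stats::rgamma(1, shape = 1 / cv^2, scale = mean_s * cv^2)
  max(d, floor_s)
}

#' Generate a synthetic membrane-potential recording
#'
#' Simulates an intracellular SPN recording under anesthesia: a two-state
#' semi-Markov alternation between a hyperpolarized down state and a
#' depolarized up state (gamma dwell times matching `osc_freq_hz`), additive
#' Gaussian membrane noise, PSP waveforms after each scheduled cortical
#' stimulus, stylized action potentials, and light flashes that -- when they
#' arrive in a down state -- trigger an up-state transition with probability
#' `light_evoke_prob` at a latency drawn from `light_latency_dist`. An evoked
#' transition overrides the next spontaneous one, so transition counts stay
#' interpretable; within one down state the earliest evoking light wins.
#'
#' @param params a [synth_params()] object.
#' @param protocol optional [protocol_spec()]; expanded with
#'   [protocol_events()] to the event schedule.
#' @param duration_s recording length (s); defaults to 2 s past the last
#'   event, or 10 s when there are none.
#' @param events optional explicit event table (`time_s`, `kind`) used instead
#'   of `protocol`.
#' @param seed RNG seed; identical `(params, protocol, seed)` give
#'   bit-identical recordings.
#' @return a `membrane_recording`: `vm` (mV), `sampling_rate_hz`,
#'   `duration_s`, `events`, and `meta` carrying the seed, the ground-truth
#'   state `transitions` table, the per-light `evoked` table, and an input
#'   resistance series.
#' @export
generate_recording <- function(params, protocol = NULL, duration_s = NULL,
                               events = NULL, seed = params$seed) {
  validate_synth_params(params)
  if (!is.null(protocol) && is.null(events)) events <- protocol_events(protocol)
  if (is.null(events))
    events <- data.frame(time_s = numeric(), kind = character())
  if (is.null(duration_s))
    duration_s <- if (nrow(events)) max(events$time_s) + 2 else 10
  if (nrow(events) && max(events$time_s) > duration_s)
    stop("generate_recording: duration too short for the event schedule")
  if (!is.null(seed)) set.seed(seed)

  fs <- params$sampling_rate_hz
  n <- round(duration_s * fs)
  cycle <- 1 / params$osc_freq_hz
  mean_up <- params$duty_up * cycle
  mean_down <- (1 - params$duty_up) * cycle
  ramp_s <- max(params$transition_ramp_ms / 1000, 1.5 / fs)

  lights <- sort(events$time_s[events$kind == "light"])
  light_used <- rep(FALSE, length(lights))
  evoked <- data.frame(time_s = numeric(), evoked = logical(),
                       latency_s = numeric(), in_down = logical())

  ## Build the state timeline sequentially, consuming light events in order.
  t <- 0; state <- "down"
  trans_t <- numeric(); trans_to <- character()
  while (t < duration_s) {
    if (state == "down") {
      t_next <- t + draw_dwell(mean_down, params$dwell_cv)
      overridden <- FALSE
      for (i in seq_along(lights)) {
        tl <- lights[i]
        if (light_used[i] || tl < t || tl >= t_next) next
        light_used[i] <- TRUE
        ev <- stats::runif(1) < params$light_evoke_prob
        lat <- if (ev) params$light_latency_dist$r(1) else NA_real_
        evoked <- rbind(evoked, data.frame(time_s = tl, evoked = ev,
                                           latency_s = lat, in_down = TRUE))
        if (ev && !overridden) {
          t_next <- tl + lat
          overridden <- TRUE
        }
      }
      ## lights later in this down state (after an override) are still in-down
      trans_t <- c(trans_t, t_next); trans_to <- c(trans_to, "up")
      state <- "up"; t <- t_next
    } else {
      t_next <- t + draw_dwell(mean_up, params$dwell_cv)
      for (i in seq_along(lights)) {
        tl <- lights[i]
        if (light_used[i] || tl < t || tl >= t_next) next
        light_used[i] <- TRUE
        evoked <- rbind(evoked, data.frame(time_s = tl, evoked = FALSE,
                                           latency_s = NA_real_, in_down = FALSE))
      }
      trans_t <- c(trans_t, t_next); trans_to <- c(trans_to, "down")
      state <- "down"; t <- t_next
    }
  }
  transitions <- data.frame(time_s = trans_t, to_state = trans_to)
  transitions <- transitions[transitions$time_s < duration_s, , drop = FALSE]

  ## Piecewise-constant state levels joined by linear ramps centered on the
  ## transition times, so the mid-level crossing sits at the nominal time.
  knot_x <- 0; knot_y <- params$down_mean_mv
  lev <- c(down = params$down_mean_mv, up = params$up_mean_mv)
  from <- params$down_mean_mv
  for (j in seq_len(nrow(transitions))) {
    tt <- transitions$time_s[j]; to <- lev[[transitions$to_state[j]]]
    knot_x <- c(knot_x, tt - ramp_s / 2, tt + ramp_s / 2)
    knot_y <- c(knot_y, from, to)
    from <- to
  }
  knot_x <- c(knot_x, duration_s + 1 / fs); knot_y <- c(knot_y, from)
  keep <- c(TRUE, diff(knot_x) > 0)
  tt_axis <- (seq_len(n) - 1) / fs
  vm <- stats::approx(knot_x[keep], knot_y[keep], xout = tt_axis, rule = 2)$y

  ## PSP waveforms after each cortical stimulus; drift multiplies the response
  stims <- sort(events$time_s[events$kind == "cortical_stim"])
  drift <- rep_len(params$plasticity_drift, length(stims))
  for (j in seq_along(stims)) {
    vm <- vm + psp_waveform(tt_axis, stims[j] + params$psp_latency_ms / 1000,
                            params$psp_amp_mv * drift[j],
                            params$psp_slope_mv_per_ms * drift[j])
  }
  ## stylized action potentials: 2 ms triangle, 60 mV
  for (ts in events$time_s[events$kind == "spike"]) {
    u <- tt_axis - ts
    vm <- vm + 60 * pmax(0, 1 - abs(u - 0.001) / 0.001)
  }
  if (params$noise_sd_mv > 0)
    vm <- vm + stats::rnorm(n, 0, params$noise_sd_mv)

  new_membrane_recording(vm, fs, duration_s, events,
    meta = list(seed = seed, transitions = transitions, evoked = evoked,
                input_resistance_mohm = rep(params$input_resistance_mohm, 6),
                params = params))
}

## PSP shape: linear rise at the configured maximal slope up to the amplitude,
## then exponential decay (tau 25 ms). The maximal 1 ms sliding-window slope of
## the noiseless waveform equals the configured slope exactly while the rise
## lasts at least 1 ms.
psp_waveform <- function(t_axis, onset_s, amp_mv, slope_mv_per_ms) {
  u <- (t_axis - onset_s) * 1000           # ms after onset
  rise_ms <- amp_mv / slope_mv_per_ms
  y <- numeric(length(u))
  r <- u > 0 & u <= rise_ms
  y[r] <- slope_mv_per_ms * u[r]
  d <- u > rise_ms
  y[d] <- amp_mv * exp(-(u[d] - rise_ms) / 25)
  y
}

#' Generate a set of PSP trial traces
#'
#' Fixture generator for the PSP pipeline: short down-state sweeps, each with
#' one cortical stimulus whose response is scaled by a per-trial drift factor
#' (the plasticity surrogate), plus optional injected baseline-shift artifacts
#' that the 1.5-SD exclusion rule should catch.
#'
#' @param params a [synth_params()].
#' @param n_trials number of trials (>= 1).
#' @param drift per-trial multiplicative slope factors, length `n_trials`.
#'   Trial `k` has maximal initial slope `psp_slope_mv_per_ms * drift[k]`
#'   (exactly, in the noiseless case).
#' @param artifact_frac fraction of trials receiving a whole-trace baseline
#'   shift of `artifact_shift_mv` (random sign).
#' @param artifact_shift_mv artifact magnitude (mV); must exceed the group
#'   noise scale for the exclusion stage to see it.
#' @param duration_s,stim_time_s sweep length and stimulus time (s).
#' @param seed RNG seed.
#' @return list of `psp_trial` objects (`vm`, `sampling_rate_hz`,
#'   `stim_time_s`), with attributes `drift` and `artifact` (ground truth).
#' @export
generate_psp_trial_set <- function(params, n_trials, drift = rep(1, n_trials),
                                   artifact_frac = 0, artifact_shift_mv = 8,
                                   duration_s = 0.6, stim_time_s = 0.1,
                                   seed = params$seed) {
  validate_synth_params(params)
  if (n_trials < 1) stop("generate_psp_trial_set: n_trials must be >= 1")
  if (length(drift) != n_trials)
    stop("generate_psp_trial_set: drift length must equal n_trials")
  if (any(drift < 0))
    stop("generate_psp_trial_set: negative slope requested (drift < 0)")
  if (!is.null(seed)) set.seed(seed)
  fs <- params$sampling_rate_hz
  tt <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  n_art <- round(artifact_frac * n_trials)
  art <- rep(FALSE, n_trials)
  if (n_art > 0) art[sample.int(n_trials, n_art)] <- TRUE
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    vm <- params$down_mean_mv +
      psp_waveform(tt, stim_time_s + params$psp_latency_ms / 1000,
                   params$psp_amp_mv * drift[k],
                   params$psp_slope_mv_per_ms * drift[k])
    if (params$noise_sd_mv > 0) vm <- vm + stats::rnorm(length(tt), 0, params$noise_sd_mv)
    if (art[k]) vm <- vm + sample(c(-1, 1), 1) * artifact_shift_mv
    trials[[k]] <- structure(list(vm = vm, sampling_rate_hz = fs,
                                  stim_time_s = stim_time_s),
                             class = "psp_trial")
  }
  structure(trials, drift = drift, artifact = art)
}

#' Sample paired light-evoked and control latency sets
#'
#' Draws `n` i.i.d. latencies from each of two named positive-support
#' distributions, emulating the paired structure of the latency analysis
#' (one light-evoked and one random-control latency per retained trial).
#'
#' @param light_dist,random_dist [latency_dist()] objects.
#' @param n number of pairs (>= 1).
#' @param seed RNG seed; draws are reproducible.
#' @return a `latency_dataset`: list with `light`, `random`, `paired = TRUE`,
#'   `n_light`, `n_random`.
#' @export
sample_latency_pairs <- function(light_dist, random_dist, n, seed = NULL) {
  if (!is_latency_dist(light_dist) || !is_latency_dist(random_dist))
    stop("sample_latency_pairs: both distributions must be latency_dist objects")
  if (n < 1) stop("sample_latency_pairs: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  new_latency_dataset(light_dist$r(n), random_dist$r(n), paired = TRUE)
}

new_latency_dataset <- function(light, random, paired = FALSE) {
  if (length(light) && any(light <= 0)) stop("latency_dataset: latencies must be positive")
  if (length(random) && any(random <= 0)) stop("latency_dataset: latencies must be positive")
  structure(list(light = light, random = random, paired = paired,
                 n_light = length(light), n_random = length(random)),
            class = "latency_dataset")
}

#' @export
print.latency_dataset <- function(x, ...) {
  cat(sprintf("latency_dataset: %d light, %d random latencies (%s)\n",
              x$n_light, x$n_random, if (x$paired) "paired" else "unpaired"))
  invisible(x)
}
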