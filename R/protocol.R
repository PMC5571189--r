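## reinforcement deliveries for one protocol event, relative to the pairing
reinforcement_events <- function(protocol, rule, event_idx, habituation) {
  shift <- protocol$reinforcement_delay_shift_s
  da <- th <- NULL
  if (protocol$light_on) {
    t_light <- protocol$light_delay_s + shift
    ## the light drives the thalamostriatal pathway directly; it drives
    ## dopamine either as a conditioned reinforcer (BSR present in the
    ## protocol) or through its novelty response on early presentations
    da_gain <- if (protocol$bsr_on) habituation
               else if (event_idx <= rule$novelty_da_events) habituation
               else 0
    th_gain <- if (protocol$thalamus_lesioned) 0 else habituation
    if (da_gain > 0) da <- data.frame(time_s = t_light, gain = da_gain)
    if (th_gain > 0) th <- data.frame(time_s = t_light, gain = th_gain)
  }
  if (protocol$bsr_on) {
    bsr <- data.frame(time_s = protocol$bsr_delay_s + shift, gain = 1)
    da <- if (is.null(da)) bsr else rbind(da, bsr)
  }
  list(da = da, th = th)
}

#' Run a plasticity protocol on the network
#'
#' Executes the three phases of the in vivo experiment: a baseline period
#' without pairings or reward, a pairing period of `n_events` STDP pairings
#' at `event_rate_hz` each followed by the protocol's reinforcement
#' components, and a test period. Each pairing seeds an eligibility trace on
#' the stimulated pathway (program A onto SPN 1); the reinforcement
#' conjunction read out through [apply_reinforcement()] updates those
#' weights, clipped to bounds. Light-evoked responses habituate
#' (`h <- h * exp(-1/habituation_tau_events)`) whenever the light occurs
#' without subsequent reward, and reset to 1 when light and BSR are paired;
#' the first `novelty_da_events` light presentations evoke dopamine
#' unconditionally.
#'
#' @param network a [make_network()] object (fresh default if `NULL`).
#' @param protocol a [protocol_spec()].
#' @param rule a [plasticity_rule_params()].
#' @param baseline_s,test_s lengths (s) of the baseline and test phases.
#' @return object of class `protocol_run`: `trajectory` (per-event mean
#'   weight of the stimulated pathway), `baseline_mean_w`, `test_mean_w`,
#'   `percent_change`, `peak_percent_change`.
#' @export
run_protocol <- function(network = NULL, protocol = protocol_spec(),
                         rule = plasticity_rule_params(),
                         baseline_s = 300, test_s = 300) {
  if (is.null(network)) network <- make_network(w_min = rule$w_min,
                                                w_max = rule$w_max)
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(rule, "plasticity_rule_params"))
  sign <- if (protocol$pairing_dt_ms > 0) +1 else -1
  path <- network$synapses$program == "A" & network$synapses$target_spn == 1L
  w0 <- mean_weight(network, "A", 1L)
  h <- 1
  traj <- data.frame(event = 0L, time_s = baseline_s,
                     mean_w = w0, dw = 0, conj = 0)
  for (i in seq_len(protocol$n_events)) {
    ev <- reinforcement_events(protocol, rule, i, h)
    upd <- apply_reinforcement(rule, sign, ev$da, ev$th)
    network$synapses$w[path] <- network$synapses$w[path] + upd$dw
    network <- clip_weights(network)
    if (protocol$light_on) {
      h <- if (protocol$bsr_on) 1 else h * exp(-1 / rule$habituation_tau_events)
    }
    traj <- rbind(traj, data.frame(
      event = i, time_s = baseline_s + i / protocol$event_rate_hz,
      mean_w = mean_weight(network, "A", 1L), dw = upd$dw, conj = upd$conj))
  }
  wt <- mean_weight(network, "A", 1L)
  structure(list(trajectory = traj, network = network,
                 baseline_mean_w = w0, test_mean_w = wt,
                 percent_change = 100 * (wt - w0) / w0,
                 peak_percent_change = 100 * (max(traj$mean_w) - w0) / w0,
                 protocol = protocol, rule = rule,
                 phase_bounds_s = c(baseline = baseline_s,
                                    test = baseline_s +
                                      protocol$n_events / protocol$event_rate_hz +
                                      test_s)),
            class = "protocol_run")
}

#' @export
print.protocol_run <- function(x, ...) {
  cat(sprintf(paste0("protocol_run: %d events, pairing %+g ms, light %s, ",
                     "BSR %s\n  weight change baseline -> test: %+.1f%% ",
                     "(peak %+.1f%%)\n"),
              x$protocol$n_events, x$protocol$pairing_dt_ms,
              if (x$protocol$light_on) "on" else "off",
              if (x$protocol$bsr_on) "on" else "off",
              x$percent_change, x$peak_percent_change))
  invisible(x)
}

#' The six modelled protocol conditions
#'
#' Positive-pairing protocol variants: pairings alone, full reinforcement
#' (light + BSR), BSR only, light only, both reinforcement components delayed
#' by 2 s, and full reinforcement with the thalamic pathway lesioned.
#'
#' @param n_events pairings per condition.
#' @return named list of [protocol_spec()] objects.
#' @export
model_conditions <- function(n_events = 60) {
  list(
    pairings_alone = protocol_spec(n_events, light_on = FALSE, bsr_on = FALSE),
    reinforced = protocol_spec(n_events, light_on = TRUE, bsr_on = TRUE),
    bsr_only = protocol_spec(n_events, light_on = FALSE, bsr_on = TRUE),
    light_only = protocol_spec(n_events, light_on = TRUE, bsr_on = FALSE),
    delayed_2s = protocol_spec(n_events, light_on = TRUE, bsr_on = TRUE,
                               reinforcement_delay_shift_s = 2),
    thalamic_lesion = protocol_spec(n_events, light_on = TRUE, bsr_on = TRUE,
                                    thalamus_lesioned = TRUE))
}

#' Final-weight sign pattern across the modelled conditions
#'
#' Runs every condition from [model_conditions()] with a fresh network and
#' labels the outcome: `"+"` (final above baseline), `"-"` (final below), or
#' `"rise-then-(-)"` when the trajectory first rises above baseline and still
#' ends below it (the light-only habituation signature).
#'
#' @param rule a [plasticity_rule_params()].
#' @param n_events pairings per condition.
#' @return data.frame (`condition`, `percent_change`, `peak_percent_change`,
#'   `sign`).
#' @export
protocol_sign_pattern <- function(rule = plasticity_rule_params(),
                                  n_events = 60) {
  conds <- model_conditions(n_events)
  rows <- lapply(names(conds), function(nm) {
    run <- run_protocol(protocol = conds[[nm]], rule = rule)
    sgn <- if (run$percent_change > 0) "+"
           else if (run$peak_percent_change > 0) "rise-then-(-)"
           else "-"
    data.frame(condition = nm, percent_change = run$percent_change,
               peak_percent_change = run$peak_percent_change, sign = sgn)
  })
  do.call(rbind, rows)
}
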