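# Brute-force Kuiper statistic: dense sweep of the ECDF-reference difference
# over the whole support, plus evaluation exactly at (and just below) the
# sample points. Independent of the package's closed-form D+/D- computation.
kuiper_oracle <- function(x, cdf, grid_n = 2e5) {
  xs <- sort(x)
  Fn <- stats::ecdf(xs)
  g <- sort(c(seq(min(xs) - 1, max(xs) + 1, length.out = grid_n),
              xs, xs - 1e-9))
  max(Fn(g) - cdf(g)) + max(cdf(g) - Fn(g))
}

# Piecewise-linear PSP-like trial: flat baseline, then linear segments of
# c(slope mV/ms, duration ms), then a plateau. Used as an analytic fixture
# for the slope operator.
ramp_trial <- function(segments, fs = 20000, stim_s = 0.1, level = -80,
                       total_s = 0.4) {
  tt <- seq(0, total_s - 1 / fs, by = 1 / fs)
  vm <- rep(level, length(tt))
  t0 <- stim_s
  v0 <- 0
  for (seg in segments) {
    sl <- seg[1]; dur <- seg[2] / 1000
    idx <- tt > t0 & tt <= t0 + dur
    vm[idx] <- level + v0 + sl * (tt[idx] - t0) * 1000
    v0 <- v0 + sl * seg[2]
    t0 <- t0 + dur
  }
  vm[tt > t0] <- level + v0
  structure(list(vm = vm, sampling_rate_hz = fs, stim_time_s = stim_s),
            class = "psp_trial")
}

# Ground-truth state intervals of a generated recording, with a guard band
# around transitions to keep ramp samples out.
state_samples <- function(rec, state = "down", guard_s = 0.05) {
  tr <- rec$meta$transitions
  tt <- time_axis(rec)
  bounds <- c(0, tr$time_s, rec$duration_s)
  states <- c("down", tr$to_state)   # state after each boundary
  keep <- rep(FALSE, length(tt))
  for (i in seq_along(states)) {
    if (states[i] != state) next
    keep <- keep | (tt >= bounds[i] + guard_s & tt < bounds[i + 1] - guard_s)
  }
  rec$vm[keep]
}

# One drift-recovery experiment: +25% multiplicative slope step with 10%
# injected artifacts, analyzed by the full exclusion -> slope -> normalize
# pipeline; returns the test-phase binned percent change.
drift_roundtrip <- function(seed, drift_factor = 1.25, n_base = 30,
                            n_test = 60) {
  sp <- synth_params(noise_sd_mv = 0.1, sampling_rate_hz = 20000, seed = seed)
  trials <- generate_psp_trial_set(
    sp, n_base + n_test,
    drift = c(rep(1, n_base), rep(drift_factor, n_test)),
    artifact_frac = 0.1, seed = seed)
  ex <- exclude_outlier_traces(trials)
  ser <- data.frame(
    trial_time_s = seq_along(trials) * 10,
    slope_mv_per_ms = vapply(trials,
                             function(x) psp_slope(x)$slope_mv_per_ms, 0),
    included = ex$included,
    phase = rep(c("baseline", "test"), c(n_base, n_test)))
  nb <- normalize_and_bin(ser, c(0, n_base * 10), bin_width_s = n_test * 10)
  list(mean = nb$bins$mean[1], sem = nb$bins$sem[1],
       fraction_excluded = ex$fraction_excluded,
       truth = attr(trials, "artifact"), included = ex$included)
}
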