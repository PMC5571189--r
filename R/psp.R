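## value of a trial trace at a checkpoint: mean vm over +/- 1 ms
checkpoint_value <- function(trial, t_s, halfwin_s = 0.001) {
  fs <- trial$sampling_rate_hz
  n <- length(trial$vm)
  i0 <- floor((t_s - halfwin_s) * fs) + 1
  i1 <- ceiling((t_s + halfwin_s) * fs) + 1
  if (t_s < 0 || t_s > (n - 1) / fs)
    stop("checkpoint outside trace extent: t = ", t_s, " s")
  mean(trial$vm[max(1, i0):min(n, i1)])
}

#' Exclude PSP traces contaminated by membrane-potential fluctuations
#'
#' Flags trials whose membrane potential deviates from the group mean by more
#' than `k_sd` group standard deviations at either of two standardized
#' checkpoints -- one shortly before the stimulus and one well after the PSP,
#' when the potential should have returned to baseline. Group mean and SD are
#' computed once over all trials (single pass), so the rule is reproducible
#' and order-independent, and re-running it on the retained set with the
#' frozen statistics changes nothing.
#'
#' @param trials list of `psp_trial` traces (each with `vm`,
#'   `sampling_rate_hz`, `stim_time_s`).
#' @param checkpoint_pre_s,checkpoint_post_s checkpoint times (s); defaults
#'   are 5 ms before and 200 ms after the stimulus.
#' @param k_sd exclusion threshold in group SDs (default 1.5).
#' @return list with `included` (logical), `fraction_excluded`, the
#'   per-checkpoint `values` matrix, and the frozen `center`/`spread`.
#' @export
exclude_outlier_traces <- function(trials, checkpoint_pre_s = NULL,
                                   checkpoint_post_s = NULL, k_sd = 1.5) {
  if (length(trials) < 3)
    stop("exclude_outlier_traces: need at least 3 trials")
  stim <- trials[[1]]$stim_time_s
  if (is.null(checkpoint_pre_s)) checkpoint_pre_s <- stim - 0.005
  if (is.null(checkpoint_post_s)) checkpoint_post_s <- stim + 0.200
  vals <- vapply(trials, function(tr)
    c(pre = checkpoint_value(tr, checkpoint_pre_s),
      post = checkpoint_value(tr, checkpoint_post_s)), c(pre = 0, post = 0))
  vals <- t(vals)
  center <- colMeans(vals)
  spread <- apply(vals, 2, stats::sd)
  dev <- abs(sweep(vals, 2, center))
  ## degenerate zero-SD checkpoint: no trial is excluded on its account
  lim <- k_sd * spread
  excl <- (spread["pre"] > 0 & dev[, "pre"] > lim["pre"]) |
          (spread["post"] > 0 & dev[, "post"] > lim["post"])
  list(included = !excl, fraction_excluded = mean(excl), values = vals,
       center = center, spread = spread, k_sd = k_sd,
       checkpoints = c(pre = checkpoint_pre_s, post = checkpoint_post_s))
}

#' Maximal initial slope of a PSP
#'
#' Measures corticostriatal efficacy as the maximum, over start positions, of
#' the least-squares slope in a sliding window (default 1 ms) on the initial
#' depolarizing phase of the PSP. The search is restricted to the first --
#' most likely monosynaptic -- component: it ends at the first local membrane
#' potential maximum after the stimulus, or at `search_limit_ms`, whichever is
#' earlier. The first `blank_ms` after the stimulus are blanked to skip the
#' stimulus artifact.
#'
#' @param trace a `psp_trial` (or any list with `vm`, `sampling_rate_hz`).
#' @param stim_time_s stimulus time (s); defaults to the trace's own.
#' @param window_ms sliding-window length (ms).
#' @param search_limit_ms hard limit of the search window after the stimulus.
#' @param blank_ms post-stimulus blanking (ms).
#' @param noise_floor_mv minimum depolarization above the pre-stimulus
#'   baseline for a response to count as a PSP; below it the trial is
#'   flagged `no_psp` and the slope is `NA`.
#' @param smooth_ms width (ms) of the centered running mean on which the
#'   slope is measured; leaves a linear rise (and hence the noiseless slope)
#'   exactly unchanged.
#' @param select_smooth_ms width (ms) of the heavier running mean used only
#'   to *select* the steepest window. Selecting on a nearly noise-free trace
#'   and then fitting the slope in that fixed window removes the upward
#'   extremum bias that taking the maximum of noisy window slopes would
#'   introduce (see the methods vignette).
#' @return list with `slope_mv_per_ms`, `window_start_s`, and `flag`
#'   (`"ok"` or `"no_psp"`).
#' @export
psp_slope <- function(trace, stim_time_s = trace$stim_time_s, window_ms = 1,
                      search_limit_ms = 25, blank_ms = 1,
                      noise_floor_mv = 1, smooth_ms = 0.5,
                      select_smooth_ms = 2) {
  if (window_ms <= 0) stop("psp_slope: window_ms must be positive")
  fs <- trace$sampling_rate_hz
  vm <- trace$vm
  i0 <- round((stim_time_s + blank_ms / 1000) * fs) + 1
  i1 <- round((stim_time_s + search_limit_ms / 1000) * fs) + 1
  if (i0 < 1 || i1 > length(vm))
    stop("psp_slope: trace does not cover the search window")
  seg <- vm[i0:i1]

  ## pre-stimulus baseline reference (robust to single-sample noise)
  j0 <- max(1, round((stim_time_s - 0.005) * fs) + 1)
  j1 <- max(1, round((stim_time_s - 0.001) * fs) + 1)
  ref <- mean(vm[j0:j1])

  sm <- running_mean(seg, smooth_ms / 1000 * fs)
  if (max(sm) - ref < noise_floor_mv)
    return(list(slope_mv_per_ms = NA_real_, window_start_s = NA_real_,
                flag = "no_psp"))
  d <- diff(sm)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  peaks <- peaks[sm[peaks] - ref >= noise_floor_mv]
  end <- if (length(peaks)) peaks[1] else length(seg)

  m <- max(2L, round(window_ms / 1000 * fs) + 1L)   # samples per window
  if (end < m)
    return(list(slope_mv_per_ms = NA_real_, window_start_s = NA_real_,
                flag = "no_psp"))
  ## closed-form LS slope over uniform x via a centered-weight convolution
  i <- seq_len(m)
  wgt <- (i - mean(i)) / sum((i - mean(i))^2) * fs / 1000  # mV/ms per sample
  win_slopes <- function(y) {
    s <- as.numeric(stats::filter(y, rev(wgt), sides = 1))
    s[m:length(y)]
  }
  ## window selection on the heavily smoothed trace, measurement on the
  ## lightly smoothed one
  hs <- running_mean(seg, select_smooth_ms / 1000 * fs)
  best <- which.max(win_slopes(hs[1:end]))
  list(slope_mv_per_ms = win_slopes(sm[1:end])[best],
       window_start_s = (i0 - 1 + best - 1) / fs,
       flag = "ok")
}

#' Baseline-normalize PSP slopes and bin the test phase
#'
#' Expresses each included trial's slope as percentage change relative to the
#' mean slope of the included baseline trials, and averages test-phase trials
#' in consecutive bins (default 5 min).
#'
#' @param series data.frame with columns `trial_time_s`, `slope_mv_per_ms`,
#'   `included` (logical), `phase` (`baseline`/`pairing`/`test`), and
#'   optionally `cell_id`.
#' @param baseline_window_s length-2 numeric, the time window whose included
#'   baseline trials define the reference mean.
#' @param bin_width_s test-phase bin width (s), default 300.
#' @return list with `series` (percent_change added; `NA` for excluded
#'   trials) and `bins`, a tidy table (`cell_id`, `bin_start_s`, `mean`,
#'   `sem`, `n`).
#' @export
normalize_and_bin <- function(series, baseline_window_s, bin_width_s = 300) {
  need <- c("trial_time_s", "slope_mv_per_ms", "included", "phase")
  if (!all(need %in% names(series)))
    stop("normalize_and_bin: series must have columns ",
         paste(need, collapse = ", "))
  if (is.null(series$cell_id)) series$cell_id <- "cell1"
  base <- series$included & series$phase == "baseline" &
    series$trial_time_s >= baseline_window_s[1] &
    series$trial_time_s <= baseline_window_s[2]
  if (!any(base)) stop("normalize_and_bin: empty baseline window")
  out <- series
  out$percent_change <- NA_real_
  for (cid in unique(series$cell_id)) {
    cc <- series$cell_id == cid
    if (!any(base & cc)) stop("normalize_and_bin: empty baseline for cell ", cid)
    bmean <- mean(series$slope_mv_per_ms[base & cc])
    sel <- cc & series$included
    out$percent_change[sel] <-
      100 * (series$slope_mv_per_ms[sel] - bmean) / bmean
  }
  test <- out[out$included & out$phase == "test", , drop = FALSE]
  if (nrow(test)) {
    t0 <- min(test$trial_time_s)
    test$bin_start_s <- t0 + floor((test$trial_time_s - t0) / bin_width_s) * bin_width_s
    agg <- do.call(rbind, lapply(
      split(test, list(test$cell_id, test$bin_start_s), drop = TRUE),
      function(g) data.frame(
        cell_id = g$cell_id[1], bin_start_s = g$bin_start_s[1],
        mean = mean(g$percent_change),
        sem = stats::sd(g$percent_change) / sqrt(nrow(g)),
        n = nrow(g))))
    rownames(agg) <- NULL
    agg <- agg[order(agg$cell_id, agg$bin_start_s), , drop = FALSE]
  } else {
    agg <- data.frame(cell_id = character(), bin_start_s = numeric(),
                      mean = numeric(), sem = numeric(), n = integer())
  }
  list(series = out, bins = agg)
}

#' Cell-health quality control of a recording
#'
#' Checks the inclusion criteria for an intracellular SPN recording: the
#' down-state mean must be more hyperpolarized than the threshold (default
#' -75 mV), action potentials must exceed the minimum amplitude (default
#' 50 mV), the input-resistance series must stay within the tolerance of its
#' initial value (default +/-10%), and baseline PSPs must reach the minimum
#' amplitude (default 5 mV). A criterion whose required annotation is missing
#' is reported `not_evaluable`, never silently passed.
#'
#' @param rec a `membrane_recording`.
#' @param criteria a [qc_criteria()] object.
#' @return data.frame (`criterion`, `status`, `value`) with attribute
#'   `overall` (`TRUE` only if every evaluable criterion passed and none was
#'   `not_evaluable`).
#' @export
qc_cell_health <- function(rec, criteria = qc_criteria()) {
  stopifnot(inherits(rec, "membrane_recording"), inherits(criteria, "qc_criteria"))
  fs <- rec$sampling_rate_hz
  tt <- time_axis(rec)

  ## down-state samples: below the 20th-percentile level, away from ramps
  thr <- stats::quantile(rec$vm, 0.2, names = FALSE, type = 7)
  down_mean <- mean(rec$vm[rec$vm <= thr])
  r1 <- list(criterion = "down_state", value = down_mean,
             status = if (down_mean < criteria$down_state_max_mv) "pass" else "fail")

  spikes <- rec$events$time_s[rec$events$kind == "spike"]
  if (length(spikes)) {
    amps <- vapply(spikes, function(ts) {
      i <- which(tt >= ts & tt <= ts + 0.004)
      j <- which(tt >= ts - 0.01 & tt < ts)
      if (!length(i) || !length(j)) return(NA_real_)
      max(rec$vm[i]) - stats::median(rec$vm[j])
    }, 0)
    amp <- max(amps, na.rm = TRUE)
    r2 <- list(criterion = "ap_amplitude", value = amp,
               status = if (amp > criteria$ap_min_amp_mv) "pass" else "fail")
  } else {
    r2 <- list(criterion = "ap_amplitude", value = NA_real_,
               status = "not_evaluable")
  }

  ir <- rec$meta$input_resistance_mohm
  if (is.numeric(ir) && length(ir) >= 2) {
    drift <- max(abs(ir / ir[1] - 1))
    r3 <- list(criterion = "input_resistance", value = drift,
               status = if (drift <= criteria$input_resistance_tolerance)
                 "pass" else "fail")
  } else {
    r3 <- list(criterion = "input_resistance", value = NA_real_,
               status = "not_evaluable")
  }

  stims <- rec$events$time_s[rec$events$kind == "cortical_stim"]
  if (length(stims)) {
    amps <- vapply(stims, function(ts) {
      i <- which(tt > ts & tt <= ts + 0.05)
      j <- which(tt >= ts - 0.01 & tt <= ts)
      if (!length(i) || !length(j)) return(NA_real_)
      max(rec$vm[i]) - stats::median(rec$vm[j])
    }, 0)
    amp <- stats::median(amps, na.rm = TRUE)
    r4 <- list(criterion = "psp_amplitude", value = amp,
               status = if (amp >= criteria$psp_min_amp_mv) "pass" else "fail")
  } else {
    r4 <- list(criterion = "psp_amplitude", value = NA_real_,
               status = "not_evaluable")
  }

  rep <- do.call(rbind, lapply(list(r1, r2, r3, r4), as.data.frame))
  attr(rep, "overall") <- all(rep$status == "pass")
  rep
}
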