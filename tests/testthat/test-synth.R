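test_that("noiseless generator alternates exactly between the configured plateaus", {
  sp <- synth_params(noise_sd_mv = 0, dwell_cv = 0, osc_freq_hz = 1,
                     sampling_rate_hz = 2000, transition_ramp_ms = 0)
  rec <- generate_recording(sp, duration_s = 4, seed = 1)
  expect_equal(sum(rec$meta$transitions$to_state == "up"), 4)
  on_down <- abs(rec$vm - sp$down_mean_mv) < 1e-9
  on_up <- abs(rec$vm - sp$up_mean_mv) < 1e-9
  # everything sits on a plateau except the single-sample transition ramps
  expect_gt(mean(on_down | on_up), 0.995)
  expect_equal(mean(on_down), 0.5, tolerance = 0.02)
  # uniform, strictly increasing time axis; finite vm
  tt <- time_axis(rec)
  expect_true(all(diff(tt) > 0))
  expect_equal(max(abs(diff(tt) - 1 / sp$sampling_rate_hz)), 0, tolerance = 1e-12)
  expect_true(all(is.finite(rec$vm)))
})

test_that("identical seed and parameters give bit-identical recordings", {
  sp <- synth_params(sampling_rate_hz = 1000, seed = 5)
  ev <- data.frame(time_s = c(2, 4.5, 7), kind = c("light", "cortical_stim", "light"))
  r1 <- generate_recording(sp, events = ev, duration_s = 10, seed = 5)
  r2 <- generate_recording(sp, events = ev, duration_s = 10, seed = 5)
  expect_identical(r1$vm, r2$vm)
  expect_identical(r1$meta$transitions, r2$meta$transitions)
  r3 <- generate_recording(sp, events = ev, duration_s = 10, seed = 6)
  expect_false(identical(r1$vm, r3$vm))
})

test_that("a point-mass light latency evokes up transitions at the scheduled delay", {
  sp <- synth_params(noise_sd_mv = 0, dwell_cv = 0, osc_freq_hz = 0.2,
                     light_evoke_prob = 1, sampling_rate_hz = 2000,
                     light_latency_dist = latency_dist("point", value = 0.1))
  ev <- data.frame(time_s = c(1, 6), kind = "light")
  rec <- generate_recording(sp, events = ev, duration_s = 10, seed = 2)
  expect_true(all(rec$meta$evoked$evoked))
  expect_equal(rec$meta$evoked$latency_s, c(0.1, 0.1))
  ups <- rec$meta$transitions$time_s[rec$meta$transitions$to_state == "up"]
  expect_equal(ups, c(1.1, 6.1), tolerance = 1 / sp$sampling_rate_hz)
})

test_that("down-state sample mean tracks the configured level within 1 mV", {
  sp <- synth_params(sampling_rate_hz = 1000, seed = 3)
  rec <- generate_recording(sp, duration_s = 60, seed = 3)
  expect_equal(mean(state_samples(rec, "down")), sp$down_mean_mv, tolerance = 1)
  expect_equal(mean(state_samples(rec, "up")), sp$up_mean_mv, tolerance = 1)
  # alternation rate within 20% of the configured slow-oscillation frequency
  n_up <- sum(rec$meta$transitions$to_state == "up")
  expect_equal(n_up / rec$duration_s, sp$osc_freq_hz, tolerance = 0.2)
})

test_that("light evocation probability is honored at binomial precision", {
  n_lights <- 400
  sp <- synth_params(osc_freq_hz = 0.05, dwell_cv = 0.3, noise_sd_mv = 1,
                     light_evoke_prob = 0.5, sampling_rate_hz = 100,
                     light_latency_dist = latency_dist("point", value = 0.1))
  ev <- data.frame(time_s = 5 + 20 * (0:(n_lights - 1)), kind = "light")
  rec <- generate_recording(sp, events = ev, duration_s = 20 * n_lights + 20,
                            seed = 6)
  evoked <- rec$meta$evoked
  down_lights <- evoked[evoked$in_down, ]
  # evoked overrides shorten down states, so somewhat under half the lights
  # land in a down state; enough remain for binomial precision
  expect_gt(nrow(down_lights), 120)
  frac <- mean(down_lights$evoked)
  expect_lt(abs(frac - 0.5), 1.96 * sqrt(0.25 / nrow(down_lights)))
  # mechanism: every evoked down-state light is followed by an up transition
  # exactly at the point-mass latency
  tr_up <- rec$meta$transitions$time_s[rec$meta$transitions$to_state == "up"]
  hit <- vapply(down_lights$time_s[down_lights$evoked], function(tl)
    any(abs(tr_up - (tl + 0.1)) <= 1.5 / sp$sampling_rate_hz), TRUE)
  expect_true(all(hit))
})

test_that("generator rejects impossible requests explicitly", {
  sp <- synth_params(sampling_rate_hz = 1000)
  ev <- data.frame(time_s = 12, kind = "light")
  expect_error(generate_recording(sp, events = ev, duration_s = 10),
               "duration too short")
  expect_error(latency_dist("norm"), "arg")
  expect_error(latency_dist("point", value = -1), "positive support")
  expect_error(latency_dist("weibull", shape = 2), "missing parameter")
  expect_error(synth_params(light_evoke_prob = 1.2), "light_evoke_prob")
  expect_error(synth_params(down_mean_mv = -60, up_mean_mv = -70),
               "hyperpolarized")
})

test_that("PSP trial sets honor per-trial drift exactly in the noiseless case", {
  sp <- synth_params(noise_sd_mv = 0, sampling_rate_hz = 20000)
  trials <- generate_psp_trial_set(sp, 4, drift = c(1, 1, 1.25, 0.8), seed = 1)
  slopes <- vapply(trials, function(x) psp_slope(x)$slope_mv_per_ms, 0)
  expect_equal(slopes, sp$psp_slope_mv_per_ms * c(1, 1, 1.25, 0.8),
               tolerance = 1e-9)
  expect_error(generate_psp_trial_set(sp, 3, drift = c(1, -0.2, 1)),
               "negative slope")
  expect_error(generate_psp_trial_set(sp, 3, drift = c(1, 1)), "drift length")
  expect_error(generate_psp_trial_set(sp, 0), "n_trials")
})

test_that("latency pair sampling is reproducible and respects degenerate distributions", {
  pm <- latency_dist("point", value = 0.1)
  d <- sample_latency_pairs(pm, pm, n = 20, seed = 1)
  expect_equal(d$light, rep(0.1, 20))
  expect_equal(d$random, rep(0.1, 20))
  ll <- latency_dist("llogis", shape = 3, scale = 0.12)
  wb <- latency_dist("weibull", shape = 1.5, scale = 0.35)
  d1 <- sample_latency_pairs(ll, wb, n = 50, seed = 9)
  d2 <- sample_latency_pairs(ll, wb, n = 50, seed = 9)
  expect_identical(d1$light, d2$light)
  expect_identical(d1$random, d2$random)
  expect_true(all(d1$light > 0) && all(d1$random > 0))
  expect_error(sample_latency_pairs(ll, wb, n = 0), "n must be")
})
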