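test_that("percentile thresholds are exact on analytic segments", {
  vm <- rep(c(-80, -60), each = 500)
  thr <- estimate_thresholds(vm)
  expect_equal(thr$down_level_mv, -80)
  expect_equal(thr$up_level_mv, -60)
  expect_equal(thr$transition_level_mv, -70)

  vm2 <- seq(-80, -60, length.out = 2001)   # uniform occupancy
  thr2 <- estimate_thresholds(vm2)
  expect_equal(thr2$down_level_mv, -76)
  expect_equal(thr2$up_level_mv, -64)
  expect_equal(thr2$transition_level_mv, -70)

  expect_error(estimate_thresholds(rep(-70, 100)), "degenerate")
})

test_that("latency extraction is exact to one sample on the degenerate generator", {
  sp <- synth_params(noise_sd_mv = 0, dwell_cv = 0, osc_freq_hz = 0.2,
                     light_evoke_prob = 1, sampling_rate_hz = 2000,
                     light_latency_dist = latency_dist("point", value = 0.1))
  ev <- data.frame(time_s = c(1, 6), kind = "light")
  rec <- generate_recording(sp, events = ev, duration_s = 10, seed = 2)
  lat <- extract_latencies(rec, seed = 1)
  expect_equal(lat$n_light, 2)
  expect_true(all(abs(lat$light - 0.1) <= 2 / sp$sampling_rate_hz))
  expect_equal(lat$n_random, lat$n_light)   # paired by construction
})

test_that("light events in the up state are excluded, about half at default duty", {
  sp <- synth_params(sampling_rate_hz = 1000, seed = 2)
  ev <- data.frame(time_s = seq(3, 280, by = 2.77), kind = "light")
  rec <- generate_recording(sp, events = ev, duration_s = 283, seed = 2)
  lat <- extract_latencies(rec, seed = 3)
  n_total <- attr(lat, "n_light_total")
  n_down <- attr(lat, "n_in_down")
  expect_gt(n_down / n_total, 0.35)
  expect_lt(n_down / n_total, 0.65)
  expect_lte(lat$n_light, n_down)
  expect_gte(lat$n_light, 0.7 * n_down)
  expect_true(all(lat$light > 0) && all(lat$random > 0))
})

test_that("log-logistic and Weibull MLE recover generating parameters within 15%", {
  n <- 177
  d <- sample_latency_pairs(latency_dist("llogis", shape = 3, scale = 0.12),
                            latency_dist("weibull", shape = 1.5, scale = 0.35),
                            n = n, seed = 21)
  fl <- fit_distribution(d$light, "llogis")
  expect_true(fl$converged)
  expect_equal(fl$params$shape, 3, tolerance = 0.15)
  expect_equal(fl$params$scale, 0.12, tolerance = 0.15)
  fr <- fit_distribution(d$random, "weibull")
  expect_true(fr$converged)
  expect_equal(fr$params$shape, 1.5, tolerance = 0.15)
  expect_equal(fr$params$scale, 0.35, tolerance = 0.15)
  # BIC identity with the correct parameter count
  expect_equal(fl$bic, 2 * log(n) - 2 * fl$loglik)
})

test_that("BIC prefers the true family and handles the nested Weibull/exponential pair", {
  set.seed(31)
  x <- stats::rexp(2000, rate = 8)
  fe <- fit_distribution(x, "exp")
  fw <- fit_distribution(x, "weibull")
  # weibull(shape ~ 1) reproduces the exponential: log-likelihoods close,
  # but the extra parameter loses on BIC
  expect_equal(fw$params$shape, 1, tolerance = 0.1)
  expect_lt(abs(fw$loglik - fe$loglik), 3)
  expect_lt(fe$bic, fw$bic)
  ranked <- select_distribution(x)
  expect_equal(ranked[[1]]$family, "exp")

  set.seed(32)
  y <- latency_dist("llogis", shape = 3, scale = 0.12)$r(2000)
  expect_equal(select_distribution(y)[[1]]$family, "llogis")
})

test_that("Kuiper statistic matches analytic geometry and the brute-force oracle", {
  # mid-quantile placement: V = 1/n exactly
  n <- 20
  x <- stats::qunif((1:n - 0.5) / n)
  kt <- kuiper_test(x, stats::punif)
  expect_equal(kt$statistic, 1 / n, tolerance = 1e-12)

  # hand-listed small samples against enumeration over all ECDF step points
  for (x5 in list(c(0.1, 0.3, 0.32, 0.7, 0.9),
                  c(0.05, 0.06, 0.07, 0.5, 0.95),
                  stats::runif(7))) {
    expect_equal(kuiper_test(sort(x5), stats::punif)$statistic,
                 kuiper_oracle(x5, stats::punif), tolerance = 1e-6)
  }
  set.seed(1)
  x <- stats::rlnorm(40, -2, 0.5)
  ref <- function(q) stats::plnorm(q, -2, 0.5)
  expect_equal(kuiper_test(x, ref)$statistic, kuiper_oracle(x, ref),
               tolerance = 1e-6)
})

test_that("Kuiper V is invariant under joint monotone transforms", {
  set.seed(7)
  x <- stats::rweibull(50, 1.5, 0.35)
  v1 <- kuiper_test(x, function(q) stats::pweibull(q, 1.5, 0.35))$statistic
  v2 <- kuiper_test(x^2, function(q) stats::pweibull(sqrt(q), 1.5, 0.35))$statistic
  v3 <- kuiper_test(log(x), function(q) stats::pweibull(exp(q), 1.5, 0.35))$statistic
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(v1, v3, tolerance = 1e-12)
})

test_that("Kuiper p-values behave sensibly and reject bad references", {
  set.seed(12)
  x <- stats::runif(100)
  kt <- kuiper_test(x, stats::punif)
  expect_gt(kt$p_value, 0.01)
  expect_true(kt$statistic >= 0 && kt$statistic <= 2)
  kt_mc <- kuiper_test(x, stats::punif, method = "mc", seed = 1)
  expect_lt(abs(kt_mc$p_value - kt$p_value), 0.05)
  # a clearly shifted sample is rejected
  expect_lt(kuiper_test(x^3, stats::punif)$p_value, 1e-4)
  expect_error(kuiper_test(x, function(q) 1 - q), "monotone")
  expect_error(kuiper_test(x, function(q) 2 * q), "\\[0, 1\\]")
  expect_error(kuiper_test(x[1:3], stats::punif), "at least 5")
})

test_that("excess probability has the right bounds, zero, and antisymmetry", {
  ll <- latency_dist("llogis", shape = 2.5, scale = 0.18)
  wb <- latency_dist("weibull", shape = 1.5, scale = 0.35)
  expect_equal(excess_probability(ll, ll), 0)
  expect_equal(excess_probability(latency_dist("point", value = 0.1),
                                  latency_dist("point", value = 0.5)), 1)
  e <- excess_probability(ll, wb)
  expect_equal(excess_probability(wb, ll), -e)
  expect_true(e >= -1 && e <= 1)
  expect_error(excess_probability(ll, wb, window = c(0.14, 0.06)), "window")
  expect_error(excess_probability(ll, wb, window = c(-0.1, 0.1)), "window")
})
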