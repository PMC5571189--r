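test_that("LIF integration matches the closed-form firing period", {
  nrn <- lif_neuron(tau_m_s = 0.02, v_thresh = 1, refractory_s = 0.002)
  dt <- 0.001
  # subthreshold steady state: silent
  sub <- simulate_lif(nrn, rep(0.9, 2000), dt)
  expect_length(sub$spike_times_s, 0)
  # zero input from rest: stays at rest exactly
  rest <- simulate_lif(nrn, rep(0, 500), dt)
  expect_true(all(rest$v == nrn$v_rest))
  # suprathreshold: inter-spike intervals within one step of the closed form
  sup <- simulate_lif(nrn, rep(1.5, 4000), dt)
  isi <- diff(sup$spike_times_s)
  expect_gt(length(isi), 5)
  expect_lt(max(abs(isi - lif_period(nrn, 1.5))), dt + 1e-12)
  expect_error(simulate_lif(nrn, rep(1, 10), dt_s = 0.01), "dt_s")
})

test_that("reinforcement kernels are causal with analytic peak and integral", {
  tt <- seq(-0.2, 3, by = 1e-4)
  k <- signal_kernel(tt, 0.05, 0.30)
  expect_true(all(k[tt <= 0] == 0))
  expect_true(all(k >= 0))
  expect_equal(max(k), 1, tolerance = 1e-6)
  tp <- log(0.30 / 0.05) / (1 / 0.05 - 1 / 0.30)
  expect_equal(tt[which.max(k)], tp, tolerance = 1e-4)
  expect_equal(kernel_peak_time(0.05, 0.30), tp)
  # quadrature vs closed-form integral
  tq <- seq(0, 10, by = 1e-4)
  expect_equal(sum(signal_kernel(tq, 0.05, 0.30)) * 1e-4,
               kernel_integral(0.05, 0.30), tolerance = 1e-3)
  # equal time constants: alpha-function limit, peak 1 at tau
  ka <- signal_kernel(tq, 0.1, 0.1)
  expect_equal(tq[which.max(ka)], 0.1, tolerance = 1e-3)
  expect_equal(max(ka), 1, tolerance = 1e-6)
})

test_that("pairings seed the correct eligibility trace and superpose additively", {
  rule <- plasticity_rule_params()
  s <- update_eligibility(NULL, dt_ms = +10, t_pairing_s = 0, rule = rule)
  expect_length(s$pot_seeds, 1)
  expect_length(s$dep_seeds, 0)
  s <- update_eligibility(s, dt_ms = -10, t_pairing_s = 5, rule = rule)
  expect_length(s$dep_seeds, 1)
  s_noop <- update_eligibility(s, dt_ms = +200, t_pairing_s = 6, rule = rule)
  expect_identical(s, s_noop)

  tt <- seq(0, 8, by = 0.01)
  s2 <- update_eligibility(update_eligibility(NULL, +10, 0, rule), +10, 2, rule)
  tr2 <- eligibility_traces(s2, tt, rule)$e_pot
  single <- function(t0) eligibility_traces(
    update_eligibility(NULL, +10, t0, rule), tt, rule)$e_pot
  expect_equal(tr2, single(0) + single(2), tolerance = 1e-12)
  # trace decays below 1% of its peak within 3 s
  expect_lt(eligibility_waveform(3, rule$elig_k, rule$elig_tau_r_s), 0.01)
  expect_equal(eligibility_waveform(rule$elig_tau_r_s, rule$elig_k,
                                    rule$elig_tau_r_s), 1)
})

test_that("reinforcement conjunction produces the observed plasticity signs", {
  rule <- plasticity_rule_params()
  at <- function(t) data.frame(time_s = t, gain = 1)
  # positive pairing + DA and Th at 1 s: potentiation
  expect_gt(apply_reinforcement(rule, +1, at(1), at(1))$dw, 0)
  # positive pairing + DA alone at 2 s (reward without the light): depression
  expect_lt(apply_reinforcement(rule, +1, at(2), NULL)$dw, 0)
  # negative pairing + DA and Th at 1 s: depression
  expect_lt(apply_reinforcement(rule, -1, at(1), at(1))$dw, 0)
  # negative pairing, no reinforcement: no change
  expect_equal(apply_reinforcement(rule, -1, NULL, NULL)$dw, 0)
  # positive pairing, no reinforcement: minor baseline depression
  expect_equal(apply_reinforcement(rule, +1, NULL, NULL)$dw,
               -rule$kappa_baseline)
})

test_that("the weight-change surface has one potentiation region with late delays depressive", {
  rule <- plasticity_rule_params()
  surf <- weight_change_surface(rule, t_da = seq(0, 3, by = 0.1))
  dd <- diag(surf$dw)
  expect_lt(dd[which.min(abs(surf$t_da - 2.5))], 0)      # 2.5 s delay: depression
  pos <- dd > 0
  runs <- rle(pos)
  expect_equal(sum(runs$values), 1)                      # single positive region
  at <- function(t) data.frame(time_s = t, gain = 1)
  expect_lte(apply_reinforcement(rule, +1, at(0.7), NULL)$dw, 0)  # DA alone
  expect_error(weight_change_surface(rule, t_da = seq(0, 4, by = 0.5)),
               "support")
})

test_that("weights stay inside hard bounds under extreme learning rates", {
  rule <- plasticity_rule_params(eta_pot = 10, eta_dep = 10)
  up <- run_protocol(protocol = protocol_spec(n_events = 20), rule = rule)
  expect_true(all(up$trajectory$mean_w <= rule$w_max + 1e-12))
  down <- run_protocol(protocol = protocol_spec(n_events = 20,
                                                pairing_dt_ms = -10),
                       rule = rule)
  expect_true(all(down$trajectory$mean_w >= rule$w_min - 1e-12))
})

test_that("zero learning rates are a fixed point to machine precision", {
  rule <- plasticity_rule_params(eta_pot = 0, eta_dep = 0, kappa_baseline = 0)
  run <- run_protocol(protocol = protocol_spec(n_events = 10), rule = rule)
  expect_true(all(run$trajectory$mean_w == run$baseline_mean_w))
  disc <- run_action_discovery(duration_s = 120, switch_time_s = 60,
                               rule = rule, seed = 2)
  expect_true(all(disc$trajectory$mean_w_A == disc$trajectory$mean_w_A[1]))
  expect_true(all(disc$trajectory$mean_w_B == disc$trajectory$mean_w_B[1]))
})

test_that("the surface agrees with a single-event protocol run", {
  rule <- plasticity_rule_params()
  surf <- weight_change_surface(rule, t_da = seq(0, 3, by = 0.25))
  i <- which(surf$t_da == 1)
  # one light-only event: DA (novelty) and Th both arrive at the 1 s light
  run <- run_protocol(protocol = protocol_spec(n_events = 1, light_on = TRUE,
                                               bsr_on = FALSE), rule = rule)
  expect_equal(run$trajectory$dw[2], surf$dw[i, i], tolerance = 1e-12)
})

test_that("light without reward habituates: early rise, final depression", {
  rule <- plasticity_rule_params()
  run <- run_protocol(protocol = protocol_spec(n_events = 60, light_on = TRUE,
                                               bsr_on = FALSE), rule = rule)
  expect_gt(run$peak_percent_change, 0)
  expect_lt(run$percent_change, 0)
  # the rise happens early (novelty-driven dopamine), before habituation bites
  traj <- run$trajectory
  expect_gt(max(traj$mean_w[traj$event <= 15]), run$baseline_mean_w)
})

test_that("action discovery extinguishes the old program and learns the new one", {
  d <- run_action_discovery(duration_s = 600, switch_time_s = 300,
                            rule = plasticity_rule_params(), seed = 3)
  tr <- d$trajectory
  i_sw <- max(which(tr$time_s < 300))
  expect_gt(tr$mean_w_A[i_sw], tr$mean_w_A[1])          # A learned pre-switch
  expect_lt(tr$mean_w_A[nrow(tr)], tr$mean_w_A[i_sw])   # A extinguished
  expect_gt(tr$mean_w_B[nrow(tr)], tr$mean_w_B[i_sw])   # B discovered

  # exact trajectory swap under A/B relabeling at the same seed
  d2 <- run_action_discovery(duration_s = 600, switch_time_s = 300,
                             rule = plasticity_rule_params(), seed = 3,
                             rewarded_first = "B")
  expect_equal(d$trajectory$mean_w_A, d2$trajectory$mean_w_B, tolerance = 1e-15)
  expect_equal(d$trajectory$mean_w_B, d2$trajectory$mean_w_A, tolerance = 1e-15)

  # reinforcement delayed past the eligibility window: the program fails to rise
  d3 <- run_action_discovery(duration_s = 600, switch_time_s = 300,
                             rule = plasticity_rule_params(), seed = 3,
                             reinforcement_delay_s = 2.5)
  expect_lte(d3$trajectory$mean_w_A[nrow(d3$trajectory)],
             d3$trajectory$mean_w_A[1])
})

test_that("network wiring matches the specified crossover architecture", {
  net <- make_network()
  s <- net$synapses
  expect_equal(nrow(s), 22)
  expect_equal(sum(s$program == "A" & s$target_spn == 1), 9)
  expect_equal(sum(s$program == "A" & s$target_spn == 2), 2)
  expect_equal(sum(s$program == "B" & s$target_spn == 2), 9)
  expect_equal(sum(s$program == "B" & s$target_spn == 1), 2)
  expect_error(make_network(n_crossover = 11), "n_crossover")
})
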