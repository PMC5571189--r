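## peak membrane response of an SPN to a unit-amplitude synaptic volley,
## used to scale the drive so that `quorum` synchronous unit weights reach
## threshold exactly
unit_volley_peak <- function(neuron, dt_s = 0.001, horizon_s = 0.12,
                             tau_syn_s = 0.005) {
  tt <- seq(0, horizon_s, by = dt_s)
  syn <- signal_kernel(tt, tau_syn_s, tau_syn_s)   # alpha function, peak 1
  probe <- lif_neuron(neuron$tau_m_s, neuron$v_rest, v_thresh = 1e9,
                      v_reset = neuron$v_reset, refractory_s = neuron$refractory_s)
  max(simulate_lif(probe, syn, dt_s)$v) - neuron$v_rest
}

## does the SPN fire to a synchronous volley with summed weight w_sum?
spn_fires <- function(neuron, w_sum, gain, dt_s = 0.001, horizon_s = 0.12,
                      tau_syn_s = 0.005) {
  tt <- seq(0, horizon_s, by = dt_s)
  syn <- gain * w_sum * signal_kernel(tt, tau_syn_s, tau_syn_s)
  length(simulate_lif(neuron, syn, dt_s)$spike_times_s) > 0
}

#' Action-discovery simulation
#'
#' Motor programs are emitted continuously with inter-event times uniform on
#' 5--20 s; each emission synchronously activates one program's cortical
#' units. An SPN that receives at least a quorum's worth of synchronous
#' synaptic drive fires, which seeds potentiation-eligible traces on the
#' active synapses onto it. Reinforcement (dopamine + thalamic input, 1 s
#' after the activation) is delivered only when the emitted program is the
#' currently rewarded one; program A is rewarded up to `switch_time_s`, then
#' program B. Reinforced traces potentiate, unreinforced ones decay through
#' the baseline drift, so the previously learned program is extinguished
#' while the newly rewarded one is discovered.
#'
#' @param network a [make_network()]; fresh default if `NULL`.
#' @param duration_s total simulated time (s); must exceed `switch_time_s`.
#' @param switch_time_s time of the reward-contingency switch (default 300 s).
#' @param rule a [plasticity_rule_params()].
#' @param seed RNG seed (event times and program choices).
#' @param rewarded_first which program is rewarded before the switch;
#'   relabeling `"A"` to `"B"` with the same seed swaps the trajectories
#'   exactly.
#' @param reinforcement_delay_s delay of the reinforcement after an
#'   activation (default 1 s).
#' @return object of class `discovery_run`: `trajectory` with per-event time,
#'   emitted program, and mean direct-path weights `mean_w_A` (A to SPN 1)
#'   and `mean_w_B` (B to SPN 2).
#' @export
run_action_discovery <- function(network = NULL, duration_s = 600,
                                 switch_time_s = 300,
                                 rule = plasticity_rule_params(), seed = 1,
                                 rewarded_first = c("A", "B"),
                                 reinforcement_delay_s = 1) {
  rewarded_first <- match.arg(rewarded_first)
  if (duration_s <= switch_time_s)
    stop("run_action_discovery: duration_s must exceed switch_time_s")
  if (is.null(network)) network <- make_network(w_min = rule$w_min,
                                                w_max = rule$w_max)
  if (!is.null(seed)) set.seed(seed)
  other <- if (rewarded_first == "A") "B" else "A"
  neuron <- lif_neuron()
  gain <- 1 / (network$quorum * unit_volley_peak(neuron))

  traj <- data.frame(time_s = 0, program = NA_character_,
                     rewarded = rewarded_first,
                     mean_w_A = mean_weight(network, "A", 1L),
                     mean_w_B = mean_weight(network, "B", 2L))
  t <- 0
  repeat {
    t <- t + stats::runif(1, 5, 20)
    if (t >= duration_s) break
    ## drawing "first-rewarded program vs the other" keeps the simulation
    ## exactly symmetric under A/B relabeling at a fixed seed
    prog <- if (stats::runif(1) < 0.5) rewarded_first else other
    rewarded_now <- if (t < switch_time_s) rewarded_first else other
    syn <- network$synapses
    for (spn in 1:2) {
      active <- syn$program == prog & syn$target_spn == spn
      if (!any(active)) next
      if (!spn_fires(neuron, sum(syn$w[active]), gain)) next
      ## pairing: active presynaptic units fired the SPN -> potentiation trace
      ev <- if (prog == rewarded_now)
        list(da = data.frame(time_s = reinforcement_delay_s, gain = 1),
             th = data.frame(time_s = reinforcement_delay_s, gain = 1))
      else list(da = NULL, th = NULL)
      upd <- apply_reinforcement(rule, +1, ev$da, ev$th)
      network$synapses$w[active] <- network$synapses$w[active] + upd$dw
      network <- clip_weights(network)
    }
    traj <- rbind(traj, data.frame(
      time_s = t, program = prog, rewarded = rewarded_now,
      mean_w_A = mean_weight(network, "A", 1L),
      mean_w_B = mean_weight(network, "B", 2L)))
  }
  structure(list(trajectory = traj, network = network,
                 switch_time_s = switch_time_s, rule = rule,
                 rewarded_first = rewarded_first, seed = seed),
            class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  tr <- x$trajectory
  i_sw <- max(which(tr$time_s < x$switch_time_s))
  cat(sprintf(paste0("discovery_run: %d emissions, switch at %g s ",
                     "(%s rewarded first)\n"),
              nrow(tr) - 1, x$switch_time_s, x$rewarded_first))
  cat(sprintf("  mean_w_A: start %.3f, at switch %.3f, end %.3f\n",
              tr$mean_w_A[1], tr$mean_w_A[i_sw], tr$mean_w_A[nrow(tr)]))
  cat(sprintf("  mean_w_B: start %.3f, at switch %.3f, end %.3f\n",
              tr$mean_w_B[1], tr$mean_w_B[i_sw], tr$mean_w_B[nrow(tr)]))
  invisible(x)
}
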