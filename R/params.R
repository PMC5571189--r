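#' Parameters of the synthetic recording generator
#'
#' Bundles the statistical structure of an anesthetized striatal
#' spiny-projection-neuron (SPN) recording that the generator emulates:
#' slow (0.5--2 Hz) alternation between a hyperpolarized down state and a
#' depolarized up state, cortically evoked PSPs with a fixed onset latency and
#' configurable initial slope, light flashes that can trigger an up-state
#' transition after a latency drawn from a named distribution, and a per-trial
#' multiplicative drift of PSP slope standing in for synaptic plasticity.
#'
#' @param osc_freq_hz slow-oscillation frequency (Hz); physiological band is
#'   0.5--2 Hz.
#' @param down_mean_mv,up_mean_mv mean membrane potential of the down and up
#'   state (mV); the down mean must be the more hyperpolarized.
#' @param noise_sd_mv SD of additive Gaussian membrane noise (mV). Zero gives
#'   the noiseless limit in which every generated quantity equals its
#'   configured value exactly (together with `dwell_cv = 0`).
#' @param psp_amp_mv PSP amplitude (mV); baseline recordings are expected to
#'   show PSPs of at least 5 mV.
#' @param psp_latency_ms PSP onset latency after the cortical stimulus (ms);
#'   default 5.2 ms, typical of a monosynaptic corticostriatal response.
#' @param psp_slope_mv_per_ms maximal initial PSP slope (mV/ms).
#' @param light_evoke_prob probability that a light flash arriving in a down
#'   state triggers an up-state transition.
#' @param light_latency_dist [latency_dist()] from which evoked transition
#'   latencies (s) are drawn.
#' @param plasticity_drift default per-trial multiplicative slope factor
#'   (scalar, or vector recycled over cortical stimuli).
#' @param dwell_cv coefficient of variation of the state dwell times
#'   (gamma-distributed); 0 makes the alternation strictly periodic.
#' @param duty_up fraction of each oscillation cycle spent in the up state.
#' @param transition_ramp_ms duration of the linear ramp joining the two state
#'   levels, centered on the nominal transition time.
#' @param sampling_rate_hz sampling rate (Hz); in vivo recordings are
#'   digitized at 20 kHz, tests typically use 1--2 kHz.
#' @param input_resistance_mohm nominal input resistance reported in the
#'   recording metadata (MOhm).
#' @param seed default RNG seed used by the generator when none is passed.
#' @return validated object of class `synth_params`.
#' @export
synth_params <- function(osc_freq_hz = 1,
                         down_mean_mv = -80,
                         up_mean_mv = -65,
                         noise_sd_mv = 1.5,
                         psp_amp_mv = 6,
                         psp_latency_ms = 5.2,
                         psp_slope_mv_per_ms = 1.7,
                         light_evoke_prob = 0.8,
                         light_latency_dist = latency_dist("llogis", shape = 2.5, scale = 0.18),
                         plasticity_drift = 1,
                         dwell_cv = 0.3,
                         duty_up = 0.5,
                         transition_ramp_ms = 10,
                         sampling_rate_hz = 20000,
                         input_resistance_mohm = 45,
                         seed = 1L) {
  p <- list(osc_freq_hz = osc_freq_hz, down_mean_mv = down_mean_mv,
            up_mean_mv = up_mean_mv, noise_sd_mv = noise_sd_mv,
            psp_amp_mv = psp_amp_mv, psp_latency_ms = psp_latency_ms,
            psp_slope_mv_per_ms = psp_slope_mv_per_ms,
            light_evoke_prob = light_evoke_prob,
            light_latency_dist = light_latency_dist,
            plasticity_drift = plasticity_drift, dwell_cv = dwell_cv,
            duty_up = duty_up, transition_ramp_ms = transition_ramp_ms,
            sampling_rate_hz = sampling_rate_hz,
            input_resistance_mohm = input_resistance_mohm,
            seed = seed)
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  stopifnot(p$osc_freq_hz > 0, p$sampling_rate_hz > 0, p$noise_sd_mv >= 0,
            p$dwell_cv >= 0, p$duty_up > 0, p$duty_up < 1,
            p$transition_ramp_ms >= 0)
  if (!(p$down_mean_mv < p$up_mean_mv))
    stop("synth_params: down_mean_mv must be more hyperpolarized than up_mean_mv")
  if (p$light_evoke_prob < 0 || p$light_evoke_prob > 1)
    stop("synth_params: light_evoke_prob must lie in [0, 1]")
  if (p$psp_amp_mv <= 0) stop("synth_params: psp_amp_mv must be positive")
  if (p$psp_slope_mv_per_ms <= 0)
    stop("synth_params: psp_slope_mv_per_ms must be positive")
  if (!is_latency_dist(p$light_latency_dist))
    stop("synth_params: light_latency_dist must be a latency_dist object")
  invisible(p)
}

#' Timed event schedule of one experimental condition
#'
#' Describes the protocol used in the plasticity experiments: pairings of a
#' cortically evoked PSP with a postsynaptic spike, repeated at a slow rate,
#' each optionally followed by a conditioned light flash and by
#' brain-stimulation reward (BSR) of the dopaminergic midbrain.
#'
#' @param n_events number of pairing events (default 60).
#' @param event_rate_hz pairing repetition rate (default 0.1 Hz).
#' @param pairing_dt_ms pre-to-post spike interval; +10 ms is a positive
#'   (pre-before-post) pairing, -10 ms a negative pairing.
#' @param light_delay_s delay of the light flash after the pairing (s).
#' @param bsr_delay_s delay of the BSR after the pairing (s).
#' @param light_on,bsr_on whether the light / BSR components are delivered.
#' @param thalamus_lesioned if `TRUE`, the thalamic reinforcement signal is
#'   silenced.
#' @param reinforcement_delay_shift_s extra delay added to both reinforcement
#'   components (2 s reproduces the delayed-reinforcement condition).
#' @return validated object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_events = 60, event_rate_hz = 0.1,
                          pairing_dt_ms = 10, light_delay_s = 1,
                          bsr_delay_s = 2, light_on = TRUE, bsr_on = TRUE,
                          thalamus_lesioned = FALSE,
                          reinforcement_delay_shift_s = 0) {
  if (n_events < 1) stop("protocol_spec: n_events must be >= 1")
  if (event_rate_hz <= 0) stop("protocol_spec: event_rate_hz must be positive")
  if (light_delay_s < 0 || bsr_delay_s < 0 || reinforcement_delay_shift_s < 0)
    stop("protocol_spec: delays must be non-negative")
  structure(list(n_events = as.integer(n_events), event_rate_hz = event_rate_hz,
                 pairing_dt_ms = pairing_dt_ms, light_delay_s = light_delay_s,
                 bsr_delay_s = bsr_delay_s, light_on = isTRUE(light_on),
                 bsr_on = isTRUE(bsr_on),
                 thalamus_lesioned = isTRUE(thalamus_lesioned),
                 reinforcement_delay_shift_s = reinforcement_delay_shift_s),
            class = "protocol_spec")
}

#' Expand a protocol into an absolute-time event table
#'
#' @param protocol a [protocol_spec()].
#' @param t0 time of the first pairing (s).
#' @return data.frame with columns `time_s`, `kind` (`trial_start`,
#'   `cortical_stim`, `spike`, `light`, `bsr`), event times trial-absolute.
#' @export
protocol_events <- function(protocol, t0 = 0) {
  stopifnot(inherits(protocol, "protocol_spec"))
  starts <- t0 + (seq_len(protocol$n_events) - 1) / protocol$event_rate_hz
  shift <- protocol$reinforcement_delay_shift_s
  ev <- list(data.frame(time_s = starts, kind = "trial_start"),
             data.frame(time_s = starts, kind = "cortical_stim"),
             data.frame(time_s = starts + protocol$pairing_dt_ms / 1000,
                        kind = "spike"))
  if (protocol$light_on)
    ev <- c(ev, list(data.frame(time_s = starts + protocol$light_delay_s + shift,
                                kind = "light")))
  if (protocol$bsr_on)
    ev <- c(ev, list(data.frame(time_s = starts + protocol$bsr_delay_s + shift,
                                kind = "bsr")))
  out <- do.call(rbind, ev)
  out[order(out$time_s, out$kind), , drop = FALSE]
}

#' Cell-health quality-control criteria
#'
#' Thresholds an intracellular SPN recording must satisfy for inclusion:
#' down-state membrane potential more hyperpolarized than -75 mV, action
#' potential amplitude above 50 mV, input resistance stable within +/- 10%,
#' and baseline PSP amplitude of at least 5 mV.
#'
#' @param down_state_max_mv maximum admissible down-state mean (mV).
#' @param ap_min_amp_mv minimum action-potential amplitude (mV).
#' @param input_resistance_tolerance admissible fractional drift of input
#'   resistance from its initial value (0.10 = +/-10%).
#' @param psp_min_amp_mv minimum baseline PSP amplitude (mV).
#' @return object of class `qc_criteria`.
#' @export
qc_criteria <- function(down_state_max_mv = -75, ap_min_amp_mv = 50,
                        input_resistance_tolerance = 0.10, psp_min_amp_mv = 5) {
  vals <- c(down_state_max_mv, ap_min_amp_mv, input_resistance_tolerance,
            psp_min_amp_mv)
  if (!all(is.finite(vals))) stop("qc_criteria: all thresholds must be finite")
  structure(list(down_state_max_mv = down_state_max_mv,
                 ap_min_amp_mv = ap_min_amp_mv,
                 input_resistance_tolerance = input_resistance_tolerance,
                 psp_min_amp_mv = psp_min_amp_mv),
            class = "qc_criteria")
}

#' Plasticity-rule parameterization
#'
#' Reference parameterization of the three-factor learning rule: a
#' timing-dependent eligibility trace seeded by pre/post pairings is read out
#' by the conjunction (pointwise minimum) of the dopaminergic and thalamic
#' reinforcement kernels. Potentiation-eligible traces that go unreinforced
#' decay the synapse by a small baseline drift `kappa_baseline`, matching the
#' minor depression seen with positive pairings alone; depression-eligible
#' traces without reinforcement leave the weight unchanged.
#'
#' The eligibility waveform is `e(t) = (t/tau_r)^k * exp(k * (1 - t/tau_r))`,
#' peaking at 1 at `t = tau_r`. The shape constants (`elig_k = 12`,
#' `elig_tau_r_s = 0.90`) were fixed by a calibration scan so that, along the
#' equal-delay diagonal of [weight_change_surface()], predicted potentiation
#' exceeds half its maximum for reinforcement delays of roughly 0.4--1.1 s
#' (see the methods vignette).
#'
#' @param eta_pot,eta_dep learning rates of the potentiation and depression
#'   pathways (>= 0).
#' @param kappa_baseline baseline depression applied per pairing event when a
#'   potentiation trace was seeded but the reinforcement conjunction was
#'   effectively absent.
#' @param habituation_tau_events e-folding constant (in events) of the
#'   habituation of light-evoked responses when the light is presented without
#'   subsequent reward.
#' @param novelty_da_events number of initial light presentations that evoke
#'   dopamine unconditionally through a novelty response.
#' @param da_block_scale,a2a_block_scale scalar attenuations in \[0, 1\]
#'   representing drug conditions: `da_block_scale` multiplies the dopamine
#'   signal, `a2a_block_scale` multiplies the potentiation integral.
#' @param elig_k,elig_tau_r_s eligibility-trace sharpness and rise scale (s).
#' @param pairing_window_ms pre/post interval window (ms) within which a
#'   pairing seeds a trace.
#' @param da_tau_rise_s,da_tau_decay_s,th_tau_rise_s,th_tau_decay_s rise and
#'   decay constants (s) of the dopamine and thalamic reinforcement kernels.
#' @param w_min,w_max hard synaptic-weight bounds.
#' @param conj_zero_frac the reinforcement conjunction counts as absent when
#'   its eligibility-weighted integral falls below this fraction of the
#'   best-case (calibrated optimum-delay) integral.
#' @param dt_slow_s integration step (s) of the slow reinforcement integrals.
#' @param integration_horizon_s length (s) of the post-pairing window over
#'   which the reinforcement integrals are evaluated.
#' @return validated object of class `plasticity_rule_params`.
#' @export
plasticity_rule_params <- function(eta_pot = 0.022, eta_dep = 0.022,
                                   kappa_baseline = 0.0015,
                                   habituation_tau_events = 5,
                                   novelty_da_events = 10,
                                   da_block_scale = 1, a2a_block_scale = 1,
                                   elig_k = 12, elig_tau_r_s = 0.90,
                                   pairing_window_ms = 30,
                                   da_tau_rise_s = 0.05, da_tau_decay_s = 0.30,
                                   th_tau_rise_s = 0.03, th_tau_decay_s = 0.20,
                                   w_min = 0, w_max = 2,
                                   conj_zero_frac = 0.01, dt_slow_s = 0.01,
                                   integration_horizon_s = 8) {
  if (any(c(eta_pot, eta_dep, kappa_baseline) < 0))
    stop("plasticity_rule_params: learning rates must be >= 0")
  for (s in c(da_block_scale, a2a_block_scale))
    if (s < 0 || s > 1)
      stop("plasticity_rule_params: drug scales must lie in [0, 1]")
  stopifnot(elig_k > 0, elig_tau_r_s > 0, pairing_window_ms > 0,
            da_tau_rise_s > 0, da_tau_decay_s > 0, th_tau_rise_s > 0,
            th_tau_decay_s > 0, w_min < w_max, conj_zero_frac >= 0,
            dt_slow_s > 0, habituation_tau_events > 0, novelty_da_events >= 0,
            integration_horizon_s > 0)
  structure(list(eta_pot = eta_pot, eta_dep = eta_dep,
                 kappa_baseline = kappa_baseline,
                 habituation_tau_events = habituation_tau_events,
                 novelty_da_events = as.integer(novelty_da_events),
                 da_block_scale = da_block_scale,
                 a2a_block_scale = a2a_block_scale,
                 elig_k = elig_k, elig_tau_r_s = elig_tau_r_s,
                 pairing_window_ms = pairing_window_ms,
                 da_tau_rise_s = da_tau_rise_s, da_tau_decay_s = da_tau_decay_s,
                 th_tau_rise_s = th_tau_rise_s, th_tau_decay_s = th_tau_decay_s,
                 w_min = w_min, w_max = w_max, conj_zero_frac = conj_zero_frac,
                 dt_slow_s = dt_slow_s,
                 integration_horizon_s = integration_horizon_s),
            class = "plasticity_rule_params")
}
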