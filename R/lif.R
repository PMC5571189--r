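#' Leaky integrate-and-fire neuron
#'
#' Membrane variable in arbitrary units: `dv/dt = (v_rest - v + I) / tau_m`,
#' a spike is emitted when `v` reaches `v_thresh`, after which `v` is reset
#' and held for the refractory period.
#'
#' @param tau_m_s membrane time constant (s).
#' @param v_rest,v_thresh,v_reset resting, threshold and reset levels;
#'   `v_reset < v_thresh` required.
#' @param refractory_s absolute refractory period (s).
#' @return object of class `lif_neuron`.
#' @export
lif_neuron <- function(tau_m_s = 0.02, v_rest = 0, v_thresh = 1, v_reset = 0,
                       refractory_s = 0.002) {
  if (tau_m_s <= 0) stop("lif_neuron: tau_m_s must be positive")
  if (!(v_reset < v_thresh)) stop("lif_neuron: v_reset must be below v_thresh")
  structure(list(tau_m_s = tau_m_s, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, refractory_s = refractory_s),
            class = "lif_neuron")
}

#' Simulate a leaky integrate-and-fire neuron
#'
#' Exact exponential integration over steps of `dt_s`, treating the input as
#' piecewise constant: `v <- I + v_rest + (v - I - v_rest) exp(-dt/tau)`.
#' Threshold crossings emit spikes, reset the membrane, and start the
#' refractory hold.
#'
#' @param neuron a [lif_neuron()].
#' @param input drive series in membrane units (the steady state under
#'   constant input `I` is `v_rest + I`).
#' @param dt_s integration step; must satisfy `dt_s <= tau_m_s / 10`.
#' @param v0 initial membrane value (defaults to `v_rest`).
#' @return list with `spike_times_s`, `v` (trajectory, reset values at spike
#'   samples), and `t` (time axis).
#' @export
simulate_lif <- function(neuron, input, dt_s, v0 = neuron$v_rest) {
  stopifnot(inherits(neuron, "lif_neuron"))
  if (dt_s > neuron$tau_m_s / 10)
    stop("simulate_lif: dt_s must be <= tau_m_s / 10")
  decay <- exp(-dt_s / neuron$tau_m_s)
  n <- length(input)
  v <- numeric(n); v_cur <- v0
  refr_until <- -Inf
  spikes <- numeric(0)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt_s
    if (t < refr_until) {
      v_cur <- neuron$v_reset
    } else {
      target <- neuron$v_rest + input[i]
      v_cur <- target + (v_cur - target) * decay
      if (v_cur >= neuron$v_thresh) {
        spikes <- c(spikes, t)
        v_cur <- neuron$v_reset
        refr_until <- t + neuron$refractory_s
      }
    }
    v[i] <- v_cur
  }
  list(spike_times_s = spikes, v = v, t = (seq_len(n) - 1) * dt_s)
}

#' Closed-form firing period of a LIF neuron under constant drive
#'
#' For constant suprathreshold input `I` the inter-spike interval is
#' `refractory + tau_m * log((v_rest + I - v_reset) / (v_rest + I - v_thresh))`.
#'
#' @param neuron a [lif_neuron()].
#' @param input constant drive.
#' @return period (s); `Inf` if the steady state is subthreshold.
#' @export
lif_period <- function(neuron, input) {
  vs <- neuron$v_rest + input
  if (vs <= neuron$v_thresh) return(Inf)
  neuron$refractory_s +
    neuron$tau_m_s * log((vs - neuron$v_reset) / (vs - neuron$v_thresh))
}
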