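---
title: "Reinforced corticostriatal STDP: model, analysis pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reinforced corticostriatal STDP: model, analysis pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatstdp)
```

# The scientific problem

Plasticity at synapses between motor cortex and striatal spiny projection
neurons (SPNs) is thought to underlie the acquisition of novel actions.
In the intact, anesthetized brain, spike-timing-dependent plasticity (STDP)
at these synapses is not determined by the millisecond-scale pre/post pairing
alone: a pairing sets up a synapse-local *eligibility trace*, and whether
lasting potentiation or depression results depends on whether behaviorally
relevant reinforcement signals — a phasic dopamine burst and a coincident
thalamostriatal depolarization, both evoked by a reward-conditioned sensory
stimulus — arrive within a roughly one-second window after the pairing.

This package implements both halves of that research program:

* a **computational model** of the three-factor rule — eligibility traces
  seeded by pre/post pairings, read out by the conjunction of delayed
  dopaminergic and thalamic signals — embedded in a small corticostriatal
  spiking network, with protocol simulation and an action-discovery
  experiment;
* an **electrophysiology analysis pipeline** for intracellular SPN
  recordings: artifact exclusion, PSP slope measurement, baseline
  normalization, cell-health checks, membrane up/down-state thresholds,
  light-evoked up-state latency statistics (distribution fitting, BIC
  selection, Kuiper's test, CDF excess probability);
* a **synthetic-data generator** that emulates the statistical structure of
  the recordings so that every pipeline stage is testable without the
  (unavailable) raw data.

# The plasticity rule

## Eligibility trace

A pre-before-post pairing within the ±30 ms STDP window seeds a
potentiation-eligible trace; post-before-pre seeds a depression-eligible
trace with the same waveform:

$$e(t) = \left(\frac{t}{\tau_r}\right)^{k} \exp\!\big(k\,(1 - t/\tau_r)\big),$$

which rises to a peak of 1 at $t = \tau_r$ and decays below 1% of its peak
within about 3 s. Traces from repeated pairings superpose additively.

## Reinforcement kernels and conjunction

Dopaminergic and thalamic reinforcement signals are modelled as impulse
responses of two chained leaky integrators — the bi-exponential
$\exp(-t/\tau_d) - \exp(-t/\tau_r)$, peak-normalized to 1
(`signal_kernel()`), with $\tau = 0.05/0.30$ s for dopamine and
$0.03/0.20$ s for the thalamic signal. Their *conjunction* is the pointwise
minimum $\min(\mathrm{DA}(t), \mathrm{Th}(t))$: both signals must be present
simultaneously for reinforcement to act. The weight update for one pairing is

$$\Delta w = \eta_{\mathrm{pot}}\!\int\! e_{\mathrm{pot}}(t)\,
  \min(\mathrm{DA}, \mathrm{Th})\,dt
  \;-\; \eta_{\mathrm{dep}}\!\int\! e_{\mathrm{dep}}(t)\,
  \min(\mathrm{DA}, \mathrm{Th})\,dt
  \;-\; \kappa\,\mathbf{1}[\,e_{\mathrm{pot}}\ \text{seeded} \wedge
  \text{conjunction absent}\,],$$

with weights clipped to $[w_{\min}, w_{\max}]$ after every update. The
baseline drift $\kappa$ applies only to *unreinforced potentiation* traces,
matching the experimental observation that positive pairings alone induce
minor depression while negative pairings alone leave efficacy unchanged.
"Conjunction absent" is made operational as the eligibility-weighted
conjunction integral falling below 1% (`conj_zero_frac`) of its best-case
value at the optimal delay; dopamine arriving alone, the thalamic signal
arriving alone, or both arriving far outside the eligibility window all
fall below this threshold and hence depress.

Drug conditions are represented only as scalar attenuations:
`da_block_scale` multiplies the dopamine signal and `a2a_block_scale` the
potentiation integral. No receptor biophysics is modelled.

## Calibration of the reference parameters

The eligibility constants are not free: the model's signature prediction is
that, for a single positive pairing, potentiation exceeds half its maximum
when both reinforcement components arrive roughly 0.4–1.1 s after the
pairing. The shape constants were therefore fixed by a calibration scan of
$(k, \tau_r)$ against that target window, *before* any test was written,
with the kernel constants held at their stated values. The scan selected
$k = 12$, $\tau_r = 0.90$ s; smaller sharpness values (e.g. $k = 5$) make
the eligibility trace too broad on its rising flank, pulling the lower
half-maximum edge down to ~0.15 s once the trace is convolved with the
conjunction waveform. All constants live in
`plasticity_rule_params()`, not in code.

```{r}
rule <- plasticity_rule_params()
surface <- weight_change_surface(rule, t_da = seq(0, 3, by = 0.05))
half_max_interval(surface)[c("lower_s", "upper_s", "peak_s")]
```

The learning rates (`eta_pot = eta_dep = 0.022`, `kappa_baseline = 0.0015`
per event) scale the per-event updates so that 60 reinforced pairings move
the mean weight by roughly +20% while 60 unreinforced positive pairings
drift it by about −9% — the qualitative magnitudes of the in vivo protocol.
Habituation of the light response uses an e-folding constant of 5 events,
and the first 10 light presentations evoke dopamine unconditionally
(novelty response); these two constants were chosen once so that light
without primary reward produces the expected transient rise followed by
net depression, and were not revisited.

## Network and protocols

The network (`make_network()`) has two populations of 11 cortical units
(motor programs A and B) and two SPNs; program A projects to SPN 1 and B to
SPN 2, with a two-cell crossover each way. Crossover synapses alone are
subthreshold: SPN firing requires a quorum (default 5) of synchronous
unit-weight inputs, enforced by integrating an alpha-function volley through
a leaky integrate-and-fire neuron (`simulate_lif()`, exact exponential
update, spike at threshold, reset, 2 ms refractory).

`run_protocol()` reproduces the experimental structure: baseline (no
pairings, no reward), 60 pairings at 0.1 Hz with the condition's
reinforcement components (light at +1 s, reward at +2 s, optional 2 s delay
shift or thalamic lesion), then a test phase. `run_action_discovery()`
emits program activations at uniform(5, 20) s intervals, reinforces the
currently rewarded program at 1 s, and switches the contingency at 300 s.
The emission draw is implemented over the labels
\{first-rewarded, other\}, which makes the simulation exactly symmetric
under A/B relabeling at a fixed seed — a property the test suite asserts.

# The analysis pipeline

## PSP slope and exclusion

Trials are excluded when the membrane potential deviates from the group
mean by more than 1.5 group SDs at either of two standardized checkpoints
(defaults: 5 ms before the stimulus, 200 ms after it — the exact positions
are not constrained by the experimental description, so they are declared
defaults, not inferred values). The group statistics are computed in a
single pass over all trials: a single pass is reproducible and
order-independent, and re-running the rule on the retained set with frozen
statistics changes nothing. With zero spread at a checkpoint the rule
retains everything rather than dividing by zero.

The efficacy measure is the maximal least-squares slope in a 1 ms sliding
window on the initial depolarizing phase, restricted to the first PSP
component (the search ends at the first local maximum after the stimulus),
with the first 1 ms after the stimulus blanked. Two numerical choices
matter:

* the slope is measured on a 0.5 ms centered running mean, which leaves a
  linear rise — and hence the noiseless slope — exactly unchanged;
* the *window is selected* on a more heavily smoothed copy (2 ms) and the
  slope then fitted in that fixed window. Taking the maximum of noisy
  window slopes is an extremum statistic with a strictly positive bias that
  does not cancel under baseline normalization; selecting the window on a
  nearly noise-free trace and measuring once removes it. The round-trip
  test (configured +25% drift recovered within the SEM) only passes with
  this two-stage estimator, and fails reproducibly without it.

Percent change is computed per cell against the mean slope of included
baseline trials, and test-phase trials are averaged in 5-min bins
(`normalize_and_bin()`). Statistical inference on the binned table (the
original analysis used a linear mixed-effects model in external software)
is deliberately out of scope; the pipeline exports the tidy table.

## Up/down states and latencies

For each light event, thresholds come from the membrane-potential histogram
of the 2 s window around that event: the down level is the 20th percentile,
the up level the 80th, and the transition level the mean of the two
(`estimate_thresholds()`, exact on analytic segments).

One design decision deserves emphasis. The 20th-percentile *level*
characterizes the down state's potential, but it cannot serve as a
*membership* cutoff: in a roughly 50/50 bimodal histogram the 20th
percentile falls inside the down mode, so only ~40% of genuine down-state
samples lie below it, and a "contiguous below-down-level segment" fragments
under membrane noise. `extract_latencies()` therefore judges state
membership (is the light in a down state; what is the surrounding down
segment) against the **transition level**, on a 25 ms centered running
mean of the trace, which reproduces the expected behavior that about half
of all light events qualify at the default duty cycle. Latency is the time
to the first upward crossing of the transition level; a seeded random
control point is drawn uniformly in the same down state up to the light
onset. The 1 s latency cap applies to the light latency (a capped light
event drops the pair); the control latency only requires an eventual
crossing.

## Distribution fitting, Kuiper's test, excess probability

Latency samples are fitted by maximum likelihood over five positive-support
candidate families — log-logistic, Weibull, lognormal, gamma, exponential —
and ranked by BIC ($k \ln n - 2\ell$), with ties broken by fewer parameters
and then fixed family order. The original analysis scanned a large family
catalogue with a helper tool and retained exactly two: log-logistic for
light-evoked latencies and Weibull for random-control latencies; the fixed
five-family set covers those two plus the standard nested alternatives and
is configurable. The log-logistic likelihood is maximized directly
(Nelder-Mead on log-transformed parameters, with moment starts from the
logistic distribution of the log latencies); the other families go through
`fitdistrplus`. Non-convergence is flagged and the family excluded from
ranking, never silently dropped.

`kuiper_test()` implements the one-sample Kuiper statistic
$V = D^+ + D^-$ — the rotation-invariant Kolmogorov–Smirnov variant, chosen
because group differences are expected in the distribution tails — with the
asymptotic series p-value under Stephens' finite-$n$ scaling
$\lambda = (\sqrt{n} + 0.155 + 0.24/\sqrt{n})\,V$. A Monte Carlo null
(`method = "mc"`) is available and recommended below $n \approx 30$. The
statistic is verified against a brute-force ECDF sweep and the test holds
its nominal 5% size within [0.04, 0.06] over 2000 null replicates at
$n = 100$.

`excess_probability()` computes
$[F_L(0.140) - F_L(0.060)] - [F_R(0.140) - F_R(0.060)]$ from the two fitted
CDFs — the probability of an up state beginning in the expected 60–140 ms
window after the light, over and above chance.

# The synthetic generator

`generate_recording()` emulates: slow up/down alternation as a two-state
semi-Markov process (gamma dwell times; mean dwell set by `osc_freq_hz` and
`duty_up`, CV by `dwell_cv`, both degenerate in the noiseless limit), state
levels −80/−65 mV joined by 10 ms linear ramps centered on the transition
times (so the mid-level crossing sits exactly at the nominal time), white
Gaussian membrane noise, PSPs with a 5.2 ms onset latency whose initial
rise is an exact linear ramp at the configured slope, stylized 2 ms
triangular spikes, and light events that — in a down state, with probability
`light_evoke_prob` — override the next spontaneous transition at a latency
drawn from a named distribution. The earliest evoking light in a down state
wins; later lights in the same down state are recorded but do not
re-override, keeping transition counts interpretable. Ground truth (state
transitions, per-light evocation, artifact flags, drift factors) travels in
the object's metadata so round-trip tests compare against the generator,
never against themselves.

What the generator does *not* emulate: the dwell-time distribution of real
up/down states is unknown (the experiments constrain only the 0.5–2 Hz
band), membrane noise is white rather than 1/f, spike waveforms are
stylized, and PSP shape is a ramp-plus-exponential rather than a synaptic
conductance. Passing round-trip tests therefore demonstrates that the
pipeline recovers known effects under the assumed statistical structure —
not that the structure matches real recordings in every respect.

# Problem sizes and numerical choices

The reinforcement integrals use a 10 ms step over an 8 s post-pairing
horizon (halving the step changes the half-maximum edges by less than one
grid cell); network integration uses 1 ms. The weight-change surface is
evaluated on a 25 ms delay grid for the reported edges. Test-suite problem
sizes — 2000 Kuiper null replicates at $n = 100$, 200 BIC replicates at
$n = 2000$, latency fits at $n = 177$, six replicate synthetic cells of 90
trials for the drift round-trip — were chosen to give the assertions
binomial or SEM-level power while keeping the default suite around half a
minute. Recordings in tests are generated at 0.1–2 kHz; the 20 kHz default
matches the acquisition rate of the real experiments and is exercised where
sample-exact latency behavior is asserted.

# Known limitations

* The rule's constants are a *reference parameterization* reproducing the
  published timing window and qualitative outcomes; the original model's
  full equations are part of a proprietary system and were not available.
  Conclusions about exact magnitudes of weight change are parameterization-
  dependent; sign patterns and orderings are the robust outputs.
* The min-conjunction is one of several defensible readouts (a product was
  the main alternative); min was chosen as the sharper implementation of
  "both signals must be present" and is declared, not attributed.
* Recordings serialize as CSV plus a JSON sidecar; no HDF5 container is
  provided.
* The Kuiper p-value is asymptotic with finite-n scaling; below
  $n \approx 30$ use the Monte Carlo option.
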