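Package: striatstdp
Title: Reward-Modulated Corticostriatal STDP Modelling and In Vivo Plasticity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying reinforcement-modulated spike-timing-dependent
    plasticity (STDP) at corticostriatal synapses. Implements a spiking
    corticostriatal network model in which a timing-dependent eligibility trace
    set up by pre/post pairings is converted into potentiation or depression by
    the delayed conjunction of dopaminergic and thalamic reinforcement signals,
    including habituation of a conditioned sensory reinforcer and an
    action-discovery simulation. Also provides an intracellular
    electrophysiology analysis pipeline: artifact exclusion of postsynaptic
    potential (PSP) traces, sliding-window PSP slope measurement, baseline
    normalization and binning, cell-health quality control, percentile-based
    membrane up/down-state thresholds, light-evoked up-state latency
    extraction, positive-support distribution fitting with BIC model selection,
    Kuiper's test, and CDF excess-probability statistics. A synthetic-data
    generator emulating anesthetized striatal recordings makes every stage
    testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    flexsurv,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
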