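# Demonstration pipeline configuration: all four stages at a small scale.
stages: [generate, psp, upstate, model]
seed: 7
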