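# Verify that the packaged CMA models predict acceptable resolutions
# (>= 2.0) at every node of a dense grid spanning the established MODR
# box, and report the working-point predictions.
name: modr-verification
seed: 1
factor_space: {source: packaged, stage: optimization}
models: {source: packaged, stage: optimization}
modr:
  box:
    A: [0.32, 0.40]
    B: [50.0, 60.0]
    C: [30.0, 40.0]
    D: [3.25, 3.75]
  levels: 9
  threshold: 2.0
validate: true
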