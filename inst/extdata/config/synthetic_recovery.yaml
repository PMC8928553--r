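# End-to-end synthetic-data run: build a three-level factorial design
# with centre-point replicates, simulate responses from the packaged
# CMA models with measurement noise, refit the declared term sets, and
# map the MODR from the refitted ground truth.
name: synthetic-recovery
seed: 1
factor_space: {source: packaged, stage: optimization}
models: {source: packaged, stage: optimization}
design:
  method: factorial
  levels: [-1, 0, 1]
  center_replicates: 3
simulate:
  noise_sd: 0.05
fit:
  responses:
    Rs_DP4_HICBG:
      transform: identity
      terms: ["1", "A", "C", "D", "B^2", "C^2", "D^2", "A*C", "A*D",
              "C*D", "A^2*B", "A^2*C", "A^2*D", "A*C*D"]
    Rs_2CBG_4CBG:
      transform: identity
      terms: ["1", "A", "B", "A^2", "B^2", "C^2", "D^2", "A*B", "A*C",
              "B*C", "B*D", "C*D", "A^2*C", "A^2*D", "A*B*C", "B*C*D"]
    Rs_4CBG_cabotegravir:
      transform: {type: power, lambda: -2}
      terms: ["1", "A", "B", "C", "D", "A^2", "B^2", "C^2", "D^2",
              "A*B", "A*C", "A*D", "B*C", "B*D", "C*D", "A^2*C",
              "A^2*D", "A*B*C", "A*C*D", "B*C*D"]
modr:
  box:
    A: [0.32, 0.40]
    B: [50.0, 60.0]
    C: [30.0, 40.0]
    D: [3.25, 3.75]
  levels: 5
  threshold: 2.0
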