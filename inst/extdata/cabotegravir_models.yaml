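# Fitted critical-method-attribute models and factor spaces for the
# cabotegravir UHPLC impurity method.  Coefficients are on coded units
# ([-1, +1] over the natural ranges below) and rounded to three
# decimals, as reported by the DoE software.
#
# transform: "identity" means the model predicts the response directly;
# a power transform {type: power, lambda: L} means the model predicts
# y^L and predictions are back-transformed as y = (model value)^(1/L).
# The Rs_4CBG_cabotegravir model carries lambda = -2 (inverse-square
# response transform): this is an inference from the reported
# working-point prediction, not a documented software setting, and can
# be overridden when loading.
factor_spaces:
  optimization:
    - {name: A, unit: mL/min, label: pump flow rate, low: 0.2, high: 0.4}
    - {name: B, unit: "%", label: final % mobile phase B in gradient, low: 50.0, high: 90.0}
    - {name: C, unit: degC, label: column temperature, low: 30.0, high: 50.0}
    - {name: D, unit: pH, label: pH of mobile phase A, low: 2.75, high: 3.75}
  screening:
    - {name: A, unit: mL/min, label: pump flow rate, low: 0.2, high: 0.4}
    - {name: B, unit: "%", label: final % mobile phase B in gradient, low: 50.0, high: 90.0}
    - {name: C, unit: pH, label: pH of mobile phase A (ammonium formate arm), low: 2.75, high: 3.75}
models:
  screening:
    - response: n_peaks_Rs_ge_2
      description: number of peaks with resolution >= 2.0
      transform: identity
      coefficients:
        "1": 6.983
        "A": 0.230
        "B": -0.229
        "C": 0.516
        "A^2": -0.074
        "B^2": -0.085
        "C^2": 0.405
        "A*B": 0.266
      anova: {r2: 0.9981, adj_r2: 0.9964, f_ratio: 595.0846}
    - response: n_peaks_tailing_le_1.2
      description: number of peaks with USP tailing factor <= 1.2
      transform: identity
      coefficients:
        "1": 5.353
        "A": 2.857
        "B": -0.627
        "C": 0.318
        "B^2": 0.745
        "C^2": -2.196
        "A*B": 0.920
        "A*B^2": -1.015
      anova: {r2: 0.9681, adj_r2: 0.9434, f_ratio: 39.0792,
              ms_lof: 0.0153, ms_lof_threshold: 0.3917}
  optimization:
    - response: Rs_DP4_HICBG
      description: resolution between impurities DP4 and HICBG
      transform: identity
      coefficients:
        "1": 3.911
        "A": 0.012
        "C": -0.461
        "D": 1.855
        "B^2": -0.033
        "C^2": 0.045
        "D^2": -0.896
        "A*C": 0.131
        "A*D": -0.073
        "C*D": -0.240
        "A^2*B": -0.008
        "A^2*C": -0.048
        "A^2*D": 0.122
        "A*C*D": 0.084
      anova: {r2: 1.0000, adj_r2: 0.9999, f_ratio: 26824.9324}
    - response: Rs_2CBG_4CBG
      description: resolution between impurities 2CBG and 4CBG
      transform: identity
      coefficients:
        "1": 2.955
        "A": 0.212
        "B": -0.492
        "A^2": -0.145
        "B^2": 0.136
        "C^2": -0.028
        "D^2": -0.035
        "A*B": 0.026
        "A*C": 0.042
        "B*C": 0.051
        "B*D": 0.010
        "C*D": -0.024
        "A^2*C": -0.039
        "A^2*D": -0.022
        "A*B*C": 0.010
        "B*C*D": 0.005
      anova: {r2: 0.9995, adj_r2: 0.9990, f_ratio: 1889.5476,
              ms_lof: 0.0005}
    - response: Rs_4CBG_cabotegravir
      description: resolution between impurity 4CBG and cabotegravir
      transform: {type: power, lambda: -2}
      coefficients:
        "1": 0.175
        "A": -0.055
        "B": 0.092
        "C": 0.009
        "D": 0.004
        "A^2": 0.033
        "B^2": 0.003
        "C^2": 0.006
        "D^2": 0.005
        "A*B": -0.034
        "A*C": -0.007
        "A*D": -0.002
        "B*C": -0.001
        "B*D": 0.001
        "C*D": 0.005
        "A^2*C": 0.006
        "A^2*D": 0.003
        "A*B*C": -0.004
        "A*C*D": -0.001
        "B*C*D": 0.001
      anova: {r2: 0.9999, adj_r2: 0.9997, f_ratio: 5330.2813,
              ms_lof: 0.0003}
working_point:
  A: 0.36
  B: 55.0
  C: 35.0
  D: 3.5
modr_box:
  A: [0.32, 0.40]
  B: [50.0, 60.0]
  C: [30.0, 40.0]
  D: [3.25, 3.75]
cma_threshold: 2.0
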