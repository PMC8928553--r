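# Independent copies of the published model tables and small oracle
# evaluators, kept separate from the package's YAML fixture so that
# tests compare two independently transcribed sources.

# optimization-stage CMA models: term label -> coefficient
oracle_opt_models <- list(
  Rs_DP4_HICBG = c(
    "1" = 3.911, "A" = 0.012, "C" = -0.461, "D" = 1.855,
    "B^2" = -0.033, "C^2" = 0.045, "D^2" = -0.896,
    "A*C" = 0.131, "A*D" = -0.073, "C*D" = -0.240,
    "A^2*B" = -0.008, "A^2*C" = -0.048, "A^2*D" = 0.122,
    "A*C*D" = 0.084),
  Rs_2CBG_4CBG = c(
    "1" = 2.955, "A" = 0.212, "B" = -0.492,
    "A^2" = -0.145, "B^2" = 0.136, "C^2" = -0.028, "D^2" = -0.035,
    "A*B" = 0.026, "A*C" = 0.042, "B*C" = 0.051, "B*D" = 0.010,
    "C*D" = -0.024, "A^2*C" = -0.039, "A^2*D" = -0.022,
    "A*B*C" = 0.010, "B*C*D" = 0.005),
  Rs_4CBG_cabotegravir = c(
    "1" = 0.175, "A" = -0.055, "B" = 0.092, "C" = 0.009, "D" = 0.004,
    "A^2" = 0.033, "B^2" = 0.003, "C^2" = 0.006, "D^2" = 0.005,
    "A*B" = -0.034, "A*C" = -0.007, "A*D" = -0.002, "B*C" = -0.001,
    "B*D" = 0.001, "C*D" = 0.005, "A^2*C" = 0.006, "A^2*D" = 0.003,
    "A*B*C" = -0.004, "A*C*D" = -0.001, "B*C*D" = 0.001))

oracle_opt_anova <- list(
  Rs_DP4_HICBG = list(r2 = 1.0000, adj_r2 = 0.9999, f_ratio = 26824.9324),
  Rs_2CBG_4CBG = list(r2 = 0.9995, adj_r2 = 0.9990, f_ratio = 1889.5476,
                      ms_lof = 0.0005),
  Rs_4CBG_cabotegravir = list(r2 = 0.9999, adj_r2 = 0.9997,
                              f_ratio = 5330.2813, ms_lof = 0.0003))

# screening-stage models (peak-count criteria)
oracle_screen_models <- list(
  n_peaks_Rs_ge_2 = c(
    "1" = 6.983, "A" = 0.230, "B" = -0.229, "C" = 0.516,
    "A^2" = -0.074, "B^2" = -0.085, "C^2" = 0.405, "A*B" = 0.266),
  "n_peaks_tailing_le_1.2" = c(
    "1" = 5.353, "A" = 2.857, "B" = -0.627, "C" = 0.318,
    "B^2" = 0.745, "C^2" = -2.196, "A*B" = 0.920, "A*B^2" = -1.015))

oracle_screen_anova <- list(
  n_peaks_Rs_ge_2 = list(r2 = 0.9981, adj_r2 = 0.9964, f_ratio = 595.0846),
  "n_peaks_tailing_le_1.2" = list(r2 = 0.9681, adj_r2 = 0.9434,
                                  f_ratio = 39.0792, ms_lof = 0.0153,
                                  ms_lof_threshold = 0.3917))

# coded working point: flow 0.36 over [0.2, 0.4], 55 %B over [50, 90],
# 35 degC over [30, 50], pH 3.5 over [2.75, 3.75]
oracle_working_point_coded <- c(A = 0.6, B = -0.75, C = -0.5, D = 0.5)

# independent monomial evaluator: parses "A^2*B"-style labels with its
# own tiny reader and multiplies powers out one factor at a time
oracle_monomial <- function(label, point) {
  if (label == "1") return(1)
  val <- 1
  for (part in strsplit(label, "*", fixed = TRUE)[[1]]) {
    bits <- strsplit(part, "^", fixed = TRUE)[[1]]
    p <- if (length(bits) == 2) as.numeric(bits[2]) else 1
    val <- val * point[[bits[1]]]^p
  }
  val
}

# term-by-term model evaluation (model scale, no back-transform)
oracle_polynomial <- function(coefs, point) {
  sum(vapply(names(coefs), function(lb) {
    coefs[[lb]] * oracle_monomial(lb, point)
  }, numeric(1)))
}
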