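test_that("a noiseless trace integrates to the specified total area", {
  pk <- cabotegravir_demo_peaks()
  ch <- simulate_chromatogram(pk, duration_min = 14)
  dt <- ch$time_min[2] - ch$time_min[1]
  total <- sum(ch$intensity) * dt
  expect_equal(total, sum(pk$area), tolerance = 1e-3)
})

test_that("a symmetric Gaussian peak measures as expected", {
  sig <- 0.05
  ch <- simulate_chromatogram(peak_spec("g", 2, area = 5, sigma_min = sig),
                              duration_min = 4)
  m <- measure_peaks(ch)
  expect_equal(nrow(m), 1)
  expect_equal(m$apex_time, 2, tolerance = 1e-3)
  expect_equal(m$width_half, 2.355 * sig, tolerance = 0.01 * 2.355 * sig)
  expect_equal(m$tailing, 1, tolerance = 0.01)
  expect_equal(m$height, 5 / (sig * sqrt(2 * pi)), tolerance = 1e-3)
})

test_that("exponential tailing raises the measured tailing factor", {
  sig <- 0.05
  ch <- simulate_chromatogram(peak_spec("t", 2, 5, sig, tau_min = 2 * sig),
                              duration_min = 4)
  m <- measure_peaks(ch)
  expect_gt(m$tailing, 1.2)
  # tailing grows monotonically with tau
  taus <- c(0, 0.5, 1, 2) * sig
  tf <- vapply(taus, function(tau) {
    measure_peaks(simulate_chromatogram(peak_spec("t", 2, 5, sig, tau),
                                        duration_min = 4))$tailing
  }, numeric(1))
  expect_true(all(diff(tf) > 0))
})

test_that("resolution follows the half-height formula and its symmetries", {
  p1 <- list(apex_time = 10, width_half = 0.2)
  p2 <- list(apex_time = 11, width_half = 0.2)
  expect_equal(resolution(p1, p2), 1.18 * 1 / 0.4)  # 2.95
  expect_equal(resolution(p1, p1), 0)
  # uniform time rescaling leaves resolution unchanged
  k <- 3.7
  q1 <- list(apex_time = k * 10, width_half = k * 0.2)
  q2 <- list(apex_time = k * 11, width_half = k * 0.2)
  expect_equal(resolution(q1, q2), resolution(p1, p2))
  # Gaussian base-width conversion ties the two formulas together
  expect_equal(resolution(p1, p2, "baseline"),
               2 * 1 / (1.699 * 0.4))
  # measured simulated peaks reproduce the arithmetic
  pk <- peak_spec(c("a", "b"), c(10, 11), area = c(5, 5),
                  sigma_min = 0.2 / 2.355)
  ch <- simulate_chromatogram(pk, duration_min = 13)
  m <- measure_peaks(ch)
  expect_equal(peak_resolutions(m), 2.95, tolerance = 0.01)
})

test_that("the ten-peak scenario yields the designed resolution census", {
  pk <- cabotegravir_demo_peaks()
  ch <- simulate_chromatogram(pk, duration_min = 14, noise_sd = 0.02,
                              drift = 0.5, seed = 17)
  m <- measure_peaks(ch, min_height = 1)
  expect_equal(nrow(m), 10)
  rs <- peak_resolutions(m)
  expect_length(rs, 9)
  # the deliberately crowded DP4/unknown pair is the single failure
  expect_equal(sum(rs >= 2.0), 8)
  expect_lt(rs[8], 2.0)
  tall <- which.max(m$height)   # the parent drug peak tails slightly
  expect_gt(m$tailing[tall], 1)
})

test_that("simulation is seed-deterministic and noise-free when asked", {
  pk <- cabotegravir_demo_peaks()
  a <- simulate_chromatogram(pk, 14, noise_sd = 0.05, seed = 1)
  b <- simulate_chromatogram(pk, 14, noise_sd = 0.05, seed = 1)
  c <- simulate_chromatogram(pk, 14, noise_sd = 0.05, seed = 2)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
  # the noiseless part is common to both seeds
  clean <- simulate_chromatogram(pk, 14)$intensity
  expect_equal(mean(a$intensity - clean), 0, tolerance = 0.005)
})

test_that("DoE response simulation reproduces the truth models", {
  fs <- cabotegravir_factor_space()
  mods <- cabotegravir_models()
  design <- candidate_grid(fs)
  exact <- simulate_doe_responses(mods, design, noise_sd = 0)
  for (nm in names(mods))
    expect_equal(exact[[nm]], evaluate_model(mods[[nm]], design))
  s1 <- simulate_doe_responses(mods, design, noise_sd = 0.05, seed = 9)
  s2 <- simulate_doe_responses(mods, design, noise_sd = 0.05, seed = 9)
  expect_identical(s1, s2)
})

test_that("refitting simulated responses recovers working-point predictions", {
  fs <- cabotegravir_factor_space()
  mods <- cabotegravir_models()
  design <- rbind(candidate_grid(fs),
                  data.frame(A = 0, B = 0, C = 0, D = 0)[rep(1, 3), ])
  resp <- simulate_doe_responses(mods, design, noise_sd = 0.05, seed = 33)
  wp <- code_point(fs, cabotegravir_working_point())
  for (nm in names(mods)) {
    fit <- fit_rsm(design, resp[[nm]], names(mods[[nm]]$coefficients),
                   transform = mods[[nm]]$transform)
    expect_equal(predict(fit, wp), evaluate_model(mods[[nm]], wp),
                 tolerance = 0.2 / 3)
  }
})
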