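test_that("cpk follows the one-sided capability definition", {
  expect_equal(cpk(3.0, 0.25, 2.0), 1 / 0.75)
  expect_equal(cpk(2.0, 0.5, 2.0), 0)
  expect_equal(cpk(3.0, 0, 2.0), 999)   # documented degenerate cap
  expect_equal(cpk(1.5, 0, 2.0), 0)
  expect_error(cpk(1, -0.1, 2), "non-negative")
})

test_that("capability maps onto two-sided normal coverage", {
  expect_equal(round(coverage_for_cpk(1.33), 2), 99.99)
  expect_equal(round(coverage_for_cpk(1), 2), 99.73)
  expect_equal(coverage_for_cpk(0), 0)
})

test_that("Monte-Carlo Cpk matches closed-form propagation on a linear model", {
  fs <- factor_space("A", low = 0.2, high = 0.4, unit = "mL/min")
  m <- response_model("R", c("1" = 3, "A" = 1))
  pert <- perturbation_spec(c(A = 0.01), n_draws = 20000, seed = 11)
  res <- monte_carlo_cpk(m, c(A = 0.3), pert, fs, lsl = 2)
  # coded sd = 0.01 / 0.1, response sd = 0.1, Cpk = 1 / 0.3
  expect_equal(res$mean, 3, tolerance = 0.005)
  expect_equal(res$sd, 0.1, tolerance = 0.02)
  expect_equal(res$cpk, 1 / 0.3, tolerance = 0.07 / (1 / 0.3))
  # bit-identical under the same seed
  res2 <- monte_carlo_cpk(m, c(A = 0.3), pert, fs, lsl = 2)
  expect_identical(res, res2)
  # zero perturbation degenerates to the capped index
  res0 <- monte_carlo_cpk(m, c(A = 0.3),
                          perturbation_spec(c(A = 0), n_draws = 100,
                                            seed = 1), fs, lsl = 2)
  expect_equal(res0$sd, 0)
  expect_equal(res0$cpk, 999)
})

test_that("Monte-Carlo error shrinks with the draw budget", {
  fs <- factor_space("A", low = 0.2, high = 0.4)
  m <- response_model("R", c("1" = 3, "A" = 1))
  est <- function(n, seed) {
    monte_carlo_cpk(m, c(A = 0.3),
                    perturbation_spec(c(A = 0.01), n_draws = n,
                                      seed = seed), fs, lsl = 2)$cpk
  }
  se_small <- sd(vapply(1:20, function(s) est(400, s), numeric(1)))
  se_large <- sd(vapply(1:20, function(s) est(1600, 100 + s), numeric(1)))
  # quadrupling the draws should about halve the standard error
  expect_gt(se_small / se_large, 1.4)
  expect_lt(se_small / se_large, 2.9)
})

test_that("smaller perturbations never hurt capability on a linear model", {
  fs <- factor_space("A", low = 0.2, high = 0.4)
  m <- response_model("R", c("1" = 3, "A" = 1))
  cpks <- vapply(c(0.02, 0.01, 0.005, 0.002), function(s) {
    monte_carlo_cpk(m, c(A = 0.3),
                    perturbation_spec(c(A = s), n_draws = 5000, seed = 4),
                    fs, lsl = 2)$cpk
  }, numeric(1))
  expect_true(all(diff(cpks) > 0))
})

brute_force_max_rect <- function(pass, xs, ys) {
  best <- -Inf
  for (l1 in 1:nrow(pass)) for (h1 in l1:nrow(pass))
    for (l2 in 1:ncol(pass)) for (h2 in l2:ncol(pass))
      if (all(pass[l1:h1, l2:h2]))
        best <- max(best, (xs[h1] - xs[l1]) * (ys[h2] - ys[l2]))
  best
}

test_that("MODR box extraction matches a brute-force rectangle scan", {
  xs <- 1:6; ys <- seq(0, 1, length.out = 5)
  # a mask with a unique known all-pass rectangle
  known <- matrix(FALSE, 6, 5)
  known[2:5, 2:4] <- TRUE
  known[3, 3] <- TRUE
  box <- extract_max_box(known, list(x = xs, y = ys))
  expect_equal(box$x, c(2, 5))
  expect_equal(box$y, ys[c(2, 4)])
  # random masks: extracted volume equals the exhaustive maximum and
  # the extracted box is genuinely all-pass
  set.seed(13)
  for (i in 1:10) {
    pass <- matrix(runif(30) < 0.6, 6, 5)
    if (!any(pass)) next
    box <- extract_max_box(pass, list(x = xs, y = ys))
    vol <- (box$x[2] - box$x[1]) * (box$y[2] - box$y[1])
    expect_equal(vol, brute_force_max_rect(pass, xs, ys))
    ix <- which(xs >= box$x[1] & xs <= box$x[2])
    iy <- which(ys >= box$y[1] & ys <= box$y[2])
    expect_true(all(pass[ix, iy]))
  }
})

test_that("the established MODR box passes every CMA everywhere", {
  mods <- cabotegravir_models()
  fs <- cabotegravir_factor_space()
  res <- map_modr(mods, fs, box = cabotegravir_modr_box(), levels = 5,
                  threshold = 2.0)
  expect_true(all(res$pass))
  expect_true(all(res$predictions >= 2.0))
  # all-pass mask: the extracted box is the whole mapped hull
  expect_equal(res$box, cabotegravir_modr_box(), tolerance = 1e-12)
  # raising a threshold can only remove passing nodes
  res_hi <- map_modr(mods, fs, box = cabotegravir_modr_box(), levels = 5,
                     threshold = c(Rs_DP4_HICBG = 2.0, Rs_2CBG_4CBG = 3.5,
                                   Rs_4CBG_cabotegravir = 2.0))
  expect_true(all(res_hi$pass <= res$pass))
})

test_that("per-node capability gates the MODR when perturbations are given", {
  mods <- cabotegravir_models()["Rs_DP4_HICBG"]
  fs <- cabotegravir_factor_space()
  pert <- perturbation_spec(n_draws = 400, seed = 5)
  res <- map_modr(mods, fs, box = cabotegravir_modr_box(), levels = 3,
                  pert = pert)
  expect_equal(dim(res$cpk), c(81, 1))
  expect_true(all(res$cpk > 0))
  expect_equal(res$pass,
               res$predictions[, 1] >= 2 & res$cpk[, 1] >= 1.33)
})

test_that("the working-point report reproduces the predicted CMAs", {
  rep <- working_point_report(cabotegravir_models(),
                              cabotegravir_working_point(),
                              cabotegravir_factor_space())
  expect_equal(rep$rounded[rep$response == "Rs_DP4_HICBG"], 4.9)
  expect_equal(rep$rounded[rep$response == "Rs_2CBG_4CBG"], 3.5)
  expect_equal(rep$prediction[rep$response == "Rs_4CBG_cabotegravir"],
               3.2, tolerance = 0.1 / 3.2)
})
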