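test_that("noiseless responses are interpolated exactly", {
  fs <- cabotegravir_factor_space()
  truth <- cabotegravir_models()$Rs_2CBG_4CBG
  design <- candidate_grid(fs)
  y <- evaluate_model(truth, design)
  fit <- fit_rsm(design, y, names(truth$coefficients))
  expect_equal(fit$coefficients, truth$coefficients, tolerance = 1e-10)
  expect_equal(fit$anova$r2, 1, tolerance = 1e-12)
})

test_that("OLS equals the normal-equation solution on a small dataset", {
  x <- c(-1, -0.5, 0, 0.5, 1)
  y <- c(1, 0.3, 0.1, 0.3, 1.1)
  fit <- fit_rsm(data.frame(A = x), y, c("1", "A", "A^2"))
  # independent direct solve of X'X beta = X'y
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(beta)),
               tolerance = 1e-10)
  # ANOVA from an explicit sum-of-squares decomposition
  fitted <- drop(X %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  expect_equal(fit$anova$r2, r2, tolerance = 1e-12)
  expect_equal(fit$anova$adj_r2, 1 - (1 - r2) * 4 / 2, tolerance = 1e-12)
  expect_equal(fit$anova$f_ratio, ((sst - sse) / 2) / (sse / 2),
               tolerance = 1e-10)
  # lm() as an independent cross-check of the same fit
  lmfit <- lm(y ~ x + I(x^2))
  expect_equal(unname(fit$coefficients), unname(coef(lmfit)),
               tolerance = 1e-10)
})

test_that("residuals are orthogonal to the model matrix", {
  set.seed(5)
  for (i in 1:20) {
    d <- data.frame(A = runif(12, -1, 1), B = runif(12, -1, 1))
    y <- rnorm(12)
    terms <- c("1", "A", "B", "A*B", "A^2")
    fit <- fit_rsm(d, y, terms)
    X <- model_matrix(terms, d)
    expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
    expect_lte(fit$anova$adj_r2, fit$anova$r2 + 1e-12)
  }
})

test_that("replicates split the residual into pure error and lack of fit", {
  d <- data.frame(A = c(-1, -1, -1, 0, 0, 0, 1, 1, 1),
                  replicate_group = rep(1:3, each = 3))
  set.seed(8)
  y <- d$A^2 + rnorm(9, 0, 0.2)  # quadratic truth, straight-line model
  fit <- fit_rsm(d, y, c("1", "A"))
  a <- fit$anova
  expect_equal(a$ss_pe + a$ss_lof, sum(fit$residuals^2), tolerance = 1e-10)
  expect_equal(a$df_pe, 6)
  expect_equal(a$df_lof, 1)
  expect_equal(a$ms_lof_threshold, qf(0.95, 1, 6) * a$ms_pe)
  # pure error agrees with a direct within-group computation
  ss_pe <- sum(tapply(y, d$replicate_group,
                      function(g) sum((g - mean(g))^2)))
  expect_equal(a$ss_pe, ss_pe, tolerance = 1e-12)
})

test_that("model significance uses a strict F threshold and the LOF gate", {
  expect_true(significance_check(list(f_ratio = 39.0792, ms_lof = 0.0153,
                                      ms_lof_threshold = 0.3917)))
  expect_true(significance_check(list(f_ratio = 595.0846)))
  expect_false(significance_check(list(f_ratio = 4.00)))
  expect_false(significance_check(list(f_ratio = 50, ms_lof = 0.5,
                                       ms_lof_threshold = 0.39)))
})

test_that("fitting errors are informative", {
  d <- data.frame(A = c(-1, 0, 1, 0.5))
  expect_error(fit_rsm(d, 1:4, c("1", "A", "A")), "duplicated")
  expect_error(fit_rsm(d, 1:3, c("1", "A")), "response length")
  expect_error(fit_rsm(d, c(1, -1, 2, 3), c("1", "A"),
                       transform = power_transform(-2)), "positive")
  d2 <- data.frame(A = c(-1, 1, -1, 1), B = c(-1, 1, -1, 1))
  expect_error(fit_rsm(d2, 1:4, c("1", "A", "B")), "collinear.*B")
})

test_that("coefficients of the CMA truth are recovered from noisy data", {
  fs <- cabotegravir_factor_space()
  truth <- cabotegravir_models()$Rs_DP4_HICBG
  design <- candidate_grid(fs)
  resp <- simulate_doe_responses(list(Rs_DP4_HICBG = truth), design,
                                 noise_sd = 0.02, seed = 21)
  fit <- fit_rsm(design, resp$Rs_DP4_HICBG, names(truth$coefficients))
  # every estimate within 3 standard errors of the generating value
  expect_true(all(abs(fit$coefficients - truth$coefficients) <=
                    3 * fit$se + 1e-9))
})
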