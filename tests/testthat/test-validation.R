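test_that("recovery is found-over-added in percent, two decimals", {
  expect_equal(recovery_percent(0.7166, 0.7185), 100.27)
  expect_equal(recovery_percent(0.7793, 0.8263), 106.03)
  expect_equal(recovery_percent(1.5, 1.5), 100.00)
  expect_error(recovery_percent(0, 1), "positive")
})

test_that("the packaged accuracy table is self-consistent", {
  acc <- validation_tables()$accuracy
  expect_equal(nrow(acc), 24)
  recomputed <- recovery_percent(acc$added_ugml, acc$found_ugml,
                                 digits = NULL)
  expect_true(all(abs(recomputed - acc$recovery_pct) <= 0.05))
})

test_that("RSD is the n-1 coefficient of variation in percent", {
  expect_equal(rsd_percent(c(5, 5, 5)), 0)
  expect_equal(rsd_percent(c(1, 2, 3)), 50)
  x <- rlnorm(10)
  expect_equal(rsd_percent(3.7 * x), rsd_percent(x))
  expect_error(rsd_percent(5), "two replicate")
})

test_that("response factors recomputed from slopes match the reported table", {
  tabs <- validation_tables()
  lin <- tabs$linearity
  ref_slope <- lin$slope[lin$analyte == "cabotegravir"]
  expect_equal(response_factor(8303, 24927), 0.33)
  expect_equal(response_factor(16291, 24927), 0.65)
  expect_equal(response_factor(24927, 24927), 1.00)
  rf <- tabs$response_factors
  for (i in seq_len(nrow(rf))) {
    slope <- lin$slope[lin$analyte == rf$analyte[i]]
    expect_equal(response_factor(slope, ref_slope), rf$response_factor[i],
                 tolerance = 0)
  }
})

test_that("linearity fitting equals hand-computed least squares", {
  exact <- fit_linearity(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r3, 1)
  x <- c(1, 2, 3, 4); y <- c(2, 3, 5, 6)
  f <- fit_linearity(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f$intercept, f$slope), unname(drop(beta)),
               tolerance = 1e-12)
  expect_equal(f$r, sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_error(fit_linearity(c(1, 1, 1), 1:3), "distinct")
})

test_that("a calibration series at realistic noise meets the r criterion", {
  conc <- seq(0.25, 1.0, length.out = 8)   # ug/mL, two replicates
  conc <- rep(conc, 2)
  set.seed(31)
  area <- 24927 * conc - 1307 + rnorm(16, 0, 0.005 * (24927 * conc))
  f <- fit_linearity(conc, area)
  expect_gte(f$r, 0.998)
  expect_equal(f$slope, 24927, tolerance = 0.03)
})

test_that("signal-to-noise uses the 2H/h pharmacopoeial form", {
  t <- seq(0, 10, by = 0.01)
  noise <- rep(c(1, -1), length.out = length(t))   # peak-to-peak 2
  y <- noise + 50 * exp(-(t - 7)^2 / (2 * 0.05^2))
  ch <- data.frame(time_min = t, intensity = y)
  expect_equal(snr(ch, peak_window = c(6.5, 7.5), noise_window = c(1, 3)),
               50, tolerance = 0.05)
  # doubling signal and noise leaves S/N unchanged
  ch2 <- data.frame(time_min = t, intensity = 2 * y)
  expect_equal(snr(ch2, c(6.5, 7.5), c(1, 3)),
               snr(ch, c(6.5, 7.5), c(1, 3)))
  # flat trace: no signal
  flat <- data.frame(time_min = t, intensity = rep(0.5, length(t)))
  expect_equal(snr(flat, c(6.5, 7.5), c(1, 3)), 0)
  expect_error(snr(ch, c(2, 7), c(1, 3)), "overlap")
})

test_that("validation screening applies the acceptance thresholds", {
  rep <- check_limits(validation_tables())
  expect_true(rep$all_pass)
  expect_true(all(rep$accuracy$pass))
  expect_true(rep$loq$pass[rep$loq$analyte == "DP4"])     # S/N 25.8, RSD 2.80
  expect_true(rep$accuracy$pass[rep$accuracy$impurity == "DP4"][1])  # 78.37%
  # boundary: S/N just below 10 fails the quantification limit
  fake <- list(loq = data.frame(analyte = "x", snr = 9.9,
                                rsd_area_pct = 1))
  expect_false(check_limits(fake)$loq$pass)
  # out-of-window recovery fails
  fake2 <- list(accuracy = data.frame(impurity = "x", level_pct = 0.05,
                                      recovery_pct = 65, rsd_pct = 1))
  expect_false(check_limits(fake2)$accuracy$pass)
})
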