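test_that("design coding switches levels and clocks at the interruption months", {
  d <- build_design(60, 29, 50)
  expect_equal(nrow(d), 60)
  expect_equal(d$nims[28], 0)
  expect_equal(d$time_after_nims[28], 0)
  expect_equal(d$covid[28], 0)
  expect_equal(d$nims[29], 1)
  expect_equal(d$time_after_nims[29], 1)
  expect_equal(d$covid[50], 1)
  expect_equal(d$time_after_covid[50], 1)
  expect_equal(d$time_after_covid[49], 0)
  # closed-form column sums
  expect_equal(sum(d$nims), 32)
  expect_equal(sum(d$covid), 11)
  expect_equal(sum(d$time_after_nims), 32 * 33 / 2)
  expect_equal(sum(d$time_after_covid), 11 * 12 / 2)
})

test_that("design construction validates interruption placement", {
  expect_error(build_design(60, 1), "m1")
  expect_error(build_design(60, 61), "m1")
  expect_error(build_design(60, 29, 29), "m2")
  expect_warning(build_design(20, 15), "12 months")
  d1 <- build_design(60, 29)
  expect_named(d1, c("time", "nims", "time_after_nims"))
  expect_null(attr(d1, "m2"))
})

test_that("OLS interpolates zero-noise data and matches the normal-equations oracle", {
  d <- build_design(60, 29, 50)
  b <- c(0.7947, 0.0040, 0.1743, 0.0271, 0.0484, 0.0309)
  f <- fit_ols(d, segmented_mean(b, 60, c(29, 50)))
  expect_equal(f$coefficients$estimate, b, tolerance = 1e-12)
  expect_equal(f$estimator, "OLS")

  fc <- fit_ols(d, rep(3.7, 60))
  expect_equal(fc$coefficients$estimate, c(3.7, 0, 0, 0, 0, 0),
               tolerance = 1e-12)

  set.seed(14)
  for (rep in 1:10) {
    y <- rnorm(60, sd = 2)
    f <- fit_ols(d, y)
    oracle <- oracle_normal_equations(d, y)
    expect_lt(max(abs(f$coefficients$estimate - oracle)) /
                max(abs(oracle)), 1e-8)
  }
})

test_that("OLS flags rank deficiency and handles missing months", {
  # m1 = 2 makes the post-interruption clock equal time - 1: collinear
  d <- suppressWarnings(build_design(30, 2))
  expect_error(fit_ols(d, rnorm(30)), "collinear")

  d60 <- build_design(60, 29, 50)
  y <- segmented_mean(c(1, 0.01, 0.2, 0, 0.1, 0), 60, c(29, 50))
  y[c(5, 40)] <- NA
  expect_warning(f <- fit_ols(d60, y), "listwise")
  expect_equal(f$n, 58)
  expect_equal(f$coefficients$estimate, c(1, 0.01, 0.2, 0, 0.1, 0),
               tolerance = 1e-10)
  expect_error(fit_ols(d60, rnorm(10)), "per design row")
})

test_that("Durbin-Watson statistic follows its closed forms", {
  expect_equal(durbin_watson(rep(1.3, 10))$statistic, 0)
  n <- 12
  alt <- rep(c(1, -1), n / 2)
  expect_equal(durbin_watson(alt)$statistic, 4 * (n - 1) / n)
  expect_warning(dw0 <- durbin_watson(rep(0, 10)), "zero")
  expect_true(is.na(dw0$statistic))
  expect_error(durbin_watson(c(1, 2)), "at least 3")

  set.seed(8)
  sims <- replicate(1000, durbin_watson(rnorm(60))$statistic)
  expect_equal(mean(sims), 2, tolerance = 0.05 / 2)
  expect_true(all(sims >= 0 & sims <= 4))

  # bootstrap p-value agrees with the normal approximation in direction
  e <- as.numeric(arima.sim(list(ar = 0.6), 80))
  pn <- durbin_watson(e)$p_value
  pb <- durbin_watson(e, method = "bootstrap", n_boot = 500)$p_value
  expect_lt(pn, 0.05)
  expect_lt(pb, 0.05)
})

test_that("Durbin-Watson statistic and design-aware p-value match lmtest", {
  skip_if_not_installed("lmtest")
  d <- build_design(60, 29, 50)
  set.seed(15)
  y <- segmented_mean(default_true_betas()$high_dose, 60, c(29, 50)) +
    rnorm(60, sd = 0.25)
  f <- fit_ols(d, y)
  X <- cbind(1, as.matrix(as.data.frame(d)))
  mine <- durbin_watson(f$residuals, X = X)
  ref <- lmtest::dwtest(lm(y ~ ., data = as.data.frame(d)),
                        alternative = "two.sided")
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 0.02)
})

test_that("AR(1) maximum likelihood matches nlme::gls and recovers exact data", {
  d <- build_design(60, 29, 50)
  b <- c(1, 0.01, 0.3, 0.02, 0.1, -0.01)
  f0 <- fit_ar1_ml(d, segmented_mean(b, 60, c(29, 50)))
  expect_equal(f0$coefficients$estimate, b, tolerance = 1e-6)

  skip_if_not_installed("nlme")
  set.seed(16)
  for (rho in c(-0.3, 0.2, 0.5)) {
    y <- segmented_mean(b, 60, c(29, 50)) + oracle_ar1_noise(60, rho, 0.3)
    mine <- fit_ar1_ml(d, y)
    df <- cbind(y = y, as.data.frame(d))
    ref <- nlme::gls(
      y ~ time + nims + time_after_nims + covid + time_after_covid,
      data = df, correlation = nlme::corAR1(form = ~time), method = "ML"
    )
    expect_equal(mine$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-5)
    expect_equal(mine$rho,
                 unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE)),
                 tolerance = 1e-4)
    expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
    expect_equal(mine$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 0.1)
  }
})

test_that("the AR(1) optimum dominates the OLS solution in likelihood", {
  d <- build_design(60, 29, 50)
  set.seed(17)
  for (rep in 1:12) {
    rho <- runif(1, -0.6, 0.8)
    y <- 2 + oracle_ar1_noise(60, rho, 0.4)
    ml <- fit_ar1_ml(d, y)
    ols <- fit_ols(d, y)
    expect_gte(ml$loglik + 1e-8, ols$loglik)
    expect_true(abs(ml$rho) < 1)
    expect_true(ml$dw >= 0 || is.na(ml$dw))
  }
})

test_that("AR(1) ML with gaps uses the full stationary covariance", {
  d <- build_design(60, 29, 50)
  set.seed(18)
  y <- segmented_mean(c(2, 0.01, 0.3, 0, 0.1, 0), 60, c(29, 50)) +
    oracle_ar1_noise(60, 0.4, 0.3)
  y[c(10, 33)] <- NA
  expect_warning(f <- fit_ar1_ml(d, y), "listwise")
  expect_equal(f$n, 58)
  expect_true(is.finite(f$loglik))
  expect_true(abs(f$rho) < 0.99)
})

test_that("estimator choice follows the serial-correlation test", {
  d <- build_design(60, 29, 50)
  mu <- segmented_mean(default_true_betas()$high_dose, 60, c(29, 50))
  set.seed(19)
  # power: strongly autocorrelated noise triggers the AR(1) refit in the
  # vast majority of draws (the trend columns absorb some serial signal,
  # so no single draw is guaranteed)
  picks <- replicate(100, {
    fit_its(d, mu + oracle_ar1_noise(60, 0.7, 0.25))$estimator
  })
  expect_gte(mean(picks == "AR1-ML"), 0.9)

  y_ar <- mu + oracle_ar1_noise(60, 0.7, 0.25)
  y_iid <- mu + rnorm(60, sd = 0.25)
  expect_equal(fit_its(d, y_iid, alpha = 1)$estimator, "AR1-ML")
  expect_equal(fit_its(d, y_iid, estimator = "ols")$estimator, "OLS")
  expect_equal(fit_its(d, y_iid, estimator = "ar1")$estimator, "AR1-ML")

  # size: under independent noise OLS is kept at least 90% of the time
  keep <- replicate(200, fit_its(d, mu + rnorm(60, sd = 0.25))$estimator)
  expect_gte(mean(keep == "OLS"), 0.9)

  # the OLS Durbin-Watson is carried on the refit for reporting
  f <- fit_its(d, y_ar, estimator = "ar1")
  fo <- fit_ols(d, y_ar)
  expect_equal(f$estimator, "AR1-ML")
  expect_equal(f$dw, durbin_watson(fo$residuals)$statistic)
})

test_that("post-interruption slopes combine baseline and trend changes", {
  d <- build_design(60, 29, 50)
  b_hd <- c(0.7947, 0.0040, 0.1743, 0.0271, 0.0484, 0.0309)
  f <- fit_ols(d, segmented_mean(b_hd, 60, c(29, 50)))
  expect_equal(post_slope(f, "after_first"), 0.0311, tolerance = 1e-10)

  b_nx <- c(0.3685, 0.0156, -0.2968, -0.0117, 0.0652, -0.0324)
  f2 <- fit_ols(d, segmented_mean(b_nx, 60, c(29, 50)))
  expect_equal(post_slope(f2, "after_first"), 0.0039, tolerance = 1e-10)
  expect_equal(post_slope(f2, "after_second"), 0.0039 - 0.0324,
               tolerance = 1e-10)

  b0 <- c(1, 0.02, 0.5, 0, 0.1, 0)
  f3 <- fit_ols(d, segmented_mean(b0, 60, c(29, 50)))
  expect_equal(post_slope(f3, "after_first"), 0.02, tolerance = 1e-10)

  d1 <- build_design(60, 29)
  f4 <- fit_ols(d1, segmented_mean(c(1, 0.02, 0.5, 0), 60, 29))
  expect_error(post_slope(f4, "after_second"), "single interruption")
})

test_that("predicted lines and counterfactual extensions behave by construction", {
  d <- build_design(60, 29, 50)
  f_flat <- fit_ols(d, rep(2, 60))
  pl <- predict_lines(f_flat)
  expect_equal(pl$fitted, rep(2, 60))
  expect_equal(pl$counterfactual_baseline, pl$fitted)

  b2 <- c(1, 0, 0.5, 0, 0, 0)
  f2 <- fit_ols(d, segmented_mean(b2, 60, c(29, 50)))
  pl2 <- predict_lines(f2)
  expect_equal(pl2$fitted - pl2$counterfactual_baseline,
               c(rep(0, 28), rep(0.5, 32)))
  expect_equal(pl2$counterfactual_pre_second, pl2$fitted)

  mu <- segmented_mean(default_true_betas()$overlap, 60, c(29, 50))
  f3 <- fit_ols(d, mu)
  expect_equal(predict_lines(f3)$fitted, mu, tolerance = 1e-10)
  # zeroing the second interruption keeps the first-segment model
  pl3 <- predict_lines(f3)
  expect_equal(pl3$counterfactual_pre_second[1:49], mu[1:49], tolerance = 1e-10)
})

test_that("residual diagnostics report ACF/PACF with white-noise bounds", {
  d <- build_design(60, 29, 50)
  set.seed(20)
  f <- fit_ols(d, 2 + rnorm(60))
  diag_out <- residual_diagnostics(f, max_lag = 15)
  expect_equal(diag_out$acf$value[1], 1)  # lag 0
  expect_equal(diag_out$bound, 1.96 / sqrt(60))
  expect_equal(nrow(diag_out$pacf), 15)

  # AR(1) rho = 0.6: lag-1 autocorrelation near 0.6 at large n
  big <- suppressWarnings(build_design(1000, 500))
  y <- 1 + oracle_ar1_noise(1000, 0.6, 1)
  fb <- fit_ols(big, y)
  db <- residual_diagnostics(fb, max_lag = 20)
  expect_equal(db$acf$value[2], 0.6, tolerance = 0.08)

  # white noise: about 5-7.5% of lags fall outside the bounds on average
  set.seed(21)
  frac <- replicate(150, {
    fw <- fit_ols(big, rnorm(1000))
    dw <- residual_diagnostics(fw, max_lag = 20)
    mean(abs(dw$acf$value[-1]) > dw$bound)
  })
  expect_lt(mean(frac), 0.09)
  expect_gt(mean(frac), 0.02)
})
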