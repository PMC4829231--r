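test_that("fit_ols reproduces exact and degenerate configurations", {
  fit <- suppressWarnings(fit_ols(data.frame(x = 0:2, y = 0:2)))
  expect_equal(fit$params$beta0, 0, tolerance = 1e-12)
  expect_equal(fit$params$beta1, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  fit2 <- fit_ols(data.frame(x = 0:2, y = c(0, 1, 0)))
  expect_equal(fit2$params$beta1, 0, tolerance = 1e-12)
  expect_equal(fit2$params$beta0, 1 / 3, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 0, tolerance = 1e-12)

  expect_error(fit_ols(data.frame(x = c(1, 1, 1), y = 1:3)), "degenerate")
  expect_error(fit_ols(data.frame(x = 1:2, y = 1:2)), "at least 3")
})

test_that("fit_ols agrees with longhand normal equations on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:50, 1)
    x <- runif(n, 0.01, 0.5)
    y <- 5.6 - 5.7 * x + rnorm(n, 0, 0.2)
    fit <- fit_ols(data.frame(x = x, y = y))
    oracle <- ols_oracle(x, y)
    expect_equal(fit$params$beta0, oracle$beta0, tolerance = 1e-10)
    expect_equal(fit$params$beta1, oracle$beta1, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
    # F-R^2 identity for the simple regression
    expect_equal(fit$f_stat,
                 fit$r_squared * (n - 2) / (1 - fit$r_squared),
                 tolerance = 1e-6)
  }
})

test_that("fit recovers seeded truth within sampling error", {
  pts <- make_points(50, beta0 = 5.6, beta1 = -5.7, sd = 0.1, seed = 7)
  fit <- fit_ols(pts)
  se <- summary(fit$model)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$params$beta0 - 5.6), 3 * se[1])
  expect_lt(abs(fit$params$beta1 + 5.7), 3 * se[2])
})

test_that("diagnostics match leave-one-out refits and hat-matrix identities", {
  pts <- make_points(20, sd = 0.15, seed = 3)
  fit <- fit_ols(pts)
  d <- fit_diagnostics(fit)
  expect_equal(sum(d$leverage), 2, tolerance = 1e-9)
  expect_true(all(d$leverage >= 0 & d$leverage <= 1))
  expect_true(all(d$cooks_d >= 0))
  expect_equal(d$studentized, loo_studentized_oracle(pts$x, pts$y),
               tolerance = 1e-9)
  # longhand leverage
  expect_equal(d$leverage,
               1 / 20 + (pts$x - mean(pts$x))^2 / sum((pts$x - mean(pts$x))^2),
               tolerance = 1e-12)
  # longhand Cook's distance from residual, leverage and residual mean square
  expect_equal(d$cooks_d,
               d$residual^2 * d$leverage /
                 (2 * fit$residual_variance * (1 - d$leverage)^2),
               tolerance = 1e-9)
})

test_that("a zero-residual point has zero studentized residual and Cook's distance", {
  # antisymmetric design: the fitted line passes exactly through (0, 0),
  # so the centre point's residual is identically zero
  pts <- data.frame(x = c(-2, -1, 0, 1, 2), y = c(-1.9, -1.1, 0, 1.1, 1.9))
  fit <- fit_ols(pts)
  d <- fit_diagnostics(fit)
  expect_equal(d$residual[3], 0)
  expect_equal(d$studentized[3], 0)
  expect_equal(d$cooks_d[3], 0)
})

test_that("a +10 sigma contaminated point dominates the diagnostics", {
  pts <- make_points(30, sd = 0.15, seed = 11)
  pts$y[17] <- pts$y[17] + 10 * 0.15
  fit <- fit_ols(pts)
  d <- fit_diagnostics(fit)
  expect_equal(which.max(abs(d$studentized)), 17)
  expect_true(d$is_outlier[17])
  flagged <- flag_outliers(d)
  expect_true(pts$year[17] %in% flagged$year)
})

test_that("outlier flagging uses strict thresholds on either rule", {
  diags <- data.frame(year = 1:4,
                      studentized = c(2.9, 3.1, 0.0, 3.0),
                      cooks_d = c(0.5, 0.0, 1.2, 1.0))
  flagged <- flag_outliers(diags)
  expect_equal(flagged$year, c(2, 3)) # exactly-at-threshold rows not flagged
})

test_that("exclusion-and-refit removes contamination and improves the slope", {
  truth_b <- 5.742
  # clean series: no exclusions, refit identical to initial fit
  clean <- make_points(30, sd = 0.05, seed = 21)
  res <- fit_with_exclusion(clean)
  expect_equal(nrow(res$excluded), 0)
  expect_equal(res$params$beta1, res$initial_fit$params$beta1)
  expect_equal(res$n_used, 30)

  # contaminated series: the shifted year is excluded and the refit is closer
  pts <- make_points(30, sd = 0.15, seed = 22)
  pts$y[5] <- pts$y[5] + 10 * 0.15
  res2 <- fit_with_exclusion(pts)
  expect_equal(res2$excluded$year, pts$year[5])
  expect_equal(res2$n_used, 29)
  err_refit <- abs(-res2$params$beta1 - truth_b)
  err_contam <- abs(-res2$initial_fit$params$beta1 - truth_b)
  expect_lt(err_refit, err_contam)

  # thresholds disabled: identical to plain OLS
  res3 <- fit_with_exclusion(pts, sr_threshold = Inf, cooks_threshold = Inf)
  expect_equal(res3$params$beta1, fit_ols(pts)$params$beta1)
  expect_equal(nrow(res3$excluded), 0)
})

test_that("exclusion refuses to drop below 3 points", {
  pts <- data.frame(year = 1:4, x = c(0.1, 0.2, 0.3, 0.4),
                    y = c(1, 1.01, 0.99, 25))
  expect_warning(res <- fit_with_exclusion(pts, sr_threshold = 0.1,
                                           cooks_threshold = 0.001),
                 "fewer than 3")
  expect_equal(res$n_used, 4)
  expect_error(fit_with_exclusion(pts[1:3, ]), "at least 4")
})

test_that("fit results serialise to JSON and CSV", {
  pts <- make_points(15, seed = 31)
  res <- fit_with_exclusion(pts)
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_fit_json(res, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$params$beta1, res$params$beta1, tolerance = 1e-12)
  expect_equal(back$n_used, 15)
  expect_equal(back$p_display, "<0.001")
  write_diagnostics_csv(res, cf)
  expect_equal(nrow(utils::read.csv(cf)), 15)
})
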