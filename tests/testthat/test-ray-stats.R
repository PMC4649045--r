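test_that("mean sensitivity follows its closed forms", {
  expect_equal(mean_sensitivity(rep(7, 10)), 0)
  expect_equal(mean_sensitivity(c(1, 3)), 100)
  a <- 4
  b <- 6
  expect_equal(
    mean_sensitivity(rep(c(a, b), 10)),
    100 * abs(2 * (b - a) / (a + b))
  )
  x <- c(3, 5, 4, 6, 2)
  expect_equal(mean_sensitivity(10 * x), mean_sensitivity(x))
  expect_error(mean_sensitivity(c(1, 0, 2)), "positive")
  expect_error(mean_sensitivity(3), "2")
})

test_that("coefficient of variation is the n-1 sd over the mean", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(8, 12)), 2 * sqrt(2) / 10)
  x <- rlnorm(20)
  expect_equal(coefficient_of_variation(5 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

test_that("expected mean sensitivity matches brute-force lognormal simulation", {
  sigma <- 0.12
  set.seed(31)
  g <- rlnorm(4e5, -sigma^2 / 2, sigma)
  ms_sim <- mean_sensitivity(g)
  expect_equal(expected_mean_sensitivity(sigma), ms_sim, tolerance = 0.01)
  expect_equal(expected_mean_sensitivity(0), 0)
  # small-sigma asymptotics: E[MS] ~ 200 * sigma / sqrt(pi)
  expect_equal(expected_mean_sensitivity(0.01), 200 * 0.01 / sqrt(pi), tolerance = 0.001)
})

test_that("inter-annual calibration hits the target measured mean sensitivity", {
  cfg <- calibrate_interannual_cv(wood_config(), 10.8)
  ms <- vapply(1:150, function(s) {
    mean_sensitivity(simulate_annual_perpar(cfg, n_years = 20, seed = s))
  }, numeric(1))
  expect_equal(mean(ms), 10.8, tolerance = 0.03 * 10.8)
})

test_that("correlation matrices agree with the textbook formula", {
  expect_error(pearson_matrix(data.frame(a = 1:2, b = 2:1)), "3")
  set.seed(18)
  df <- as.data.frame(matrix(rnorm(18 * 4), 18, 4))
  pm <- pearson_matrix(df)
  expect_equal(diag(pm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(pm$r, t(pm$r))
  # independent oracle: direct formulas
  for (i in 1:3) {
    for (j in (i + 1):4) {
      x <- df[[i]]
      y <- df[[j]]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      tstat <- r * sqrt((18 - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), 16)
      expect_equal(pm$r[i, j], r, tolerance = 1e-12)
      expect_equal(pm$p[i, j], p, tolerance = 1e-9)
    }
  }
  # perfect linear relation
  df2 <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = rnorm(10))
  expect_equal(pearson_matrix(df2)$r["x", "y"], 1)
  # degenerate column flagged, not silently zero
  expect_warning(pm3 <- pearson_matrix(data.frame(a = rnorm(10), b = rep(1, 10))), "zero-variance")
  expect_true(all(is.na(pm3$r[, "b"])))
  td <- tidy(pm)
  expect_identical(nrow(td), 6L)
  expect_true(all(c("var1", "var2", "r", "p", "signif") %in% names(td)))
})

test_that("paired comparisons reproduce hand-computed t statistics", {
  b <- c(10, 20, 30, 40)
  a <- b + c(1, 1, 1, 3) # differences: mean 1.5, sd 1, n 4 -> t = 3
  tt <- paired_t_test(a, b)
  expect_equal(tt$statistic, 3)
  expect_equal(tt$df, 3)
  expect_equal(tt$p_value, 2 * stats::pt(-3, 3))
  # sign convention: positive when the first sample is larger
  expect_gt(paired_t_test(a, b)$statistic, 0)
  expect_lt(paired_t_test(b, a)$statistic, 0)
  expect_error(paired_t_test(a, a), "zero variance")
  expect_error(paired_t_test(a, b[1:3]), "equal length")
  # two-sample fallback
  t2 <- paired_t_test(rnorm(10, 1), rnorm(12), paired = FALSE)
  expect_s3_class(tidy(t2), "tbl_df")
})

test_that("allometric fits agree with the normal-equation oracle", {
  set.seed(5)
  x <- runif(40, 1, 100)
  y <- 3 + 0.8 * x + rnorm(40, 0, 4)
  fit <- fit_allometry(data.frame(len = x, area = y), len, area)
  # oracle: closed-form least squares
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  # R^2 equals the squared Pearson correlation
  expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)
  # exact line (summary.lm warns about the perfect fit; the fit is the point)
  perfect <- suppressWarnings(fit_allometry(data.frame(x = x, y = 2 * x + 1), x, y))
  expect_equal(perfect$r_squared, 1)
  expect_error(fit_allometry(data.frame(x = rep(1, 5), y = rnorm(5)), x, y), "constant")
  expect_identical(nrow(tidy(fit)), 2L)
  expect_equal(glance(fit)$r_squared, fit$r_squared)
})
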