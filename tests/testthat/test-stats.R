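# Statistical workflow: correlations, partial correlations, CIs, t-tests,
# regression, power analysis, normality checks, and the report assembly.

test_that("pearson: perfect line, null case, hand-computed small vector", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  set.seed(81)
  xn <- rnorm(500); yn <- rnorm(500)
  expect_lt(abs(pearson(xn, yn)$r), 3 / sqrt(500))
  # hand computation: r = sum(dx*dy) / sqrt(sum(dx^2) * sum(dy^2))
  ct <- pearson(c(1, 2, 3, 4), c(2, 4, 5, 9))
  expect_equal(ct$r, 11 / sqrt(130), tolerance = 1e-12)
  expect_equal(ct$r_squared, ct$r^2, tolerance = 1e-12)
  expect_identical(ct$n, 4L)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("partial correlation: no-adjustment identity and confounder removal", {
  set.seed(82)
  x <- rnorm(200); y <- rnorm(200)
  expect_equal(partial_correlation(x, y)$r, pearson(x, y)$r)
  # y driven by a control, x independent: partial r collapses to noise scale
  z <- rnorm(200)
  y2 <- 3 * z + rnorm(200, sd = 0.1)
  pc <- partial_correlation(x, y2, cbind(z))
  expect_lt(abs(pc$r), 3 / sqrt(200))
  expect_identical(pc$df, 200L - 3L)
})

test_that("partial correlation matches the precision-matrix identity", {
  set.seed(83)
  for (i in 1:10) {
    n <- 120
    ctrl <- matrix(rnorm(n * 3), n, 3)
    x <- ctrl %*% runif(3) + rnorm(n)
    y <- ctrl %*% runif(3) + 0.3 * x + rnorm(n)
    pc <- partial_correlation(as.numeric(x), as.numeric(y), ctrl)
    omega <- solve(stats::cor(cbind(x, y, ctrl)))
    expect_equal(pc$r, -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2]),
                 tolerance = 1e-10)
  }
  expect_error(partial_correlation(rnorm(50), rnorm(50),
                                   cbind(1:50, 2 * (1:50))),
               "collinear")
})

test_that("one-sample CI: constant vector, tabulated-t hand value, monotone width", {
  expect_equal(unname(one_sample_ci(rep(4, 6))), c(4, 4, 4))
  ci <- one_sample_ci(c(1, 2, 3, 4, 5))
  # t(4, 0.975) = 2.776445; half-width = t * sd / sqrt(n)
  half <- 2.776445 * sqrt(2.5) / sqrt(5)
  expect_equal(unname(ci), c(3, 3 - half, 3 + half), tolerance = 1e-6)
  w90 <- diff(one_sample_ci(c(1, 2, 3, 4, 5), 0.90)[2:3])
  w99 <- diff(one_sample_ci(c(1, 2, 3, 4, 5), 0.99)[2:3])
  expect_lt(w90, w99)
  expect_error(one_sample_ci(3), "at least 2")
})

test_that("t-test: identical and shifted groups, pooled hand formula, Levene gate", {
  set.seed(84)
  g <- rnorm(30)
  expect_equal(independent_t_test(g, g)$mean_diff, 0)
  expect_equal(independent_t_test(g, g + 5)$mean_diff, -5)
  g1 <- rnorm(25, sd = 1); g2 <- rnorm(20, mean = 0.5, sd = 1)
  tt <- independent_t_test(g1, g2)
  expect_identical(tt$equal_var_assumed, tt$levene_p > 0.05)
  if (tt$equal_var_assumed) {
    n1 <- length(g1); n2 <- length(g2)
    sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tman <- (mean(g1) - mean(g2)) / se
    expect_equal(tt$t, tman, tolerance = 1e-12)
    expect_equal(tt$p_value, 2 * pt(-abs(tman), n1 + n2 - 2),
                 tolerance = 1e-12)
  }
  # grossly heteroscedastic: the gate must switch to Welch
  g3 <- rnorm(60, sd = 0.2); g4 <- rnorm(60, sd = 6)
  tt2 <- independent_t_test(g3, g4)
  expect_false(tt2$equal_var_assumed)
  expect_lt(tt2$levene_p, 0.05)
})

test_that("linear regression: noiseless line, hand SE on a 6-point set", {
  x <- c(10, 20, 30, 40, 50, 60)
  fit0 <- linear_regression(x, 0.17 * x + 180)
  expect_equal(fit0$slope, 0.17, tolerance = 1e-12)
  expect_equal(fit0$intercept, 180, tolerance = 1e-9)
  expect_equal(fit0$slope_ci_low, fit0$slope_ci_high, tolerance = 1e-9)
  set.seed(85)
  y <- 0.5 * x + rnorm(6)
  fit <- linear_regression(x, y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / 4
  se <- sqrt(s2 / sum((x - mean(x))^2))
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$slope_se, se, tolerance = 1e-12)
  expect_equal(fit$slope_ci_high - fit$slope, qt(0.975, 4) * se,
               tolerance = 1e-12)
  # regression is not symmetric in x and y
  expect_false(isTRUE(all.equal(linear_regression(y, x)$slope, 1 / b)))
  expect_error(linear_regression(rep(2, 5), rnorm(5)), "zero predictor")
})

test_that("correlation power: size under the null, monotonicity, MC check", {
  expect_equal(power_correlation(50, 0, 0.05), 0.05, tolerance = 1e-12)
  expect_lt(power_correlation(50, 0.3, 0.05),
            power_correlation(100, 0.3, 0.05))
  expect_lt(power_correlation(100, 0.2, 0.05),
            power_correlation(100, 0.3, 0.05))
  # Monte-Carlo rejection rate of the exact test at n = 30, rho = 0.5
  set.seed(86)
  nrep <- 4000
  rej <- 0L
  for (i in 1:nrep) {
    x <- rnorm(30)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(30)
    r <- cor(x, y)
    tv <- r * sqrt(28 / (1 - r^2))
    if (2 * pt(-abs(tv), 28) < 0.05) rej <- rej + 1L
  }
  phat <- rej / nrep
  pth <- power_correlation(30, 0.5, 0.05)
  # Fisher-z approximation against the simulated truth, 99% MC band + slack
  expect_lt(abs(phat - pth), 2.58 * sqrt(phat * (1 - phat) / nrep) + 0.02)
})

test_that("minimum detectable correlation inverts the power function", {
  rho <- min_detectable_correlation(100, 0.90, 0.05)
  expect_equal(power_correlation(100, rho, 0.05), 0.90, tolerance = 1e-6)
  expect_lt(min_detectable_correlation(100, 0.051, 0.05), 0.02)
  expect_error(min_detectable_correlation(100, 1.5), "power")
})

test_that("normality tests behave under null and exponential alternatives", {
  set.seed(87)
  null_pass <- 0L
  for (i in 1:50) {
    p <- normality_tests(rnorm(100))
    if (all(p > 0.05)) null_pass <- null_pass + 1L
  }
  expect_gte(null_pass, 45L)   # >= 90% of null runs undisturbed
  sw_reject <- 0L
  for (i in 1:20)
    if (normality_tests(rexp(200))["sw_p"] < 0.05) sw_reject <- sw_reject + 1L
  expect_identical(sw_reject, 20L)
  expect_error(normality_tests(rep(1, 10)), "constant")
})

test_that("study analysis report is complete, flagged and order-invariant", {
  coh <- sample_cohort(cohort_params(n = 60, seed = 21))
  rep1 <- run_study_analysis(coh)
  expect_identical(nrow(rep1$correlations), 18L)      # 6 predictors x 3
  expect_identical(nrow(rep1$partial_correlations), 3L)
  expect_identical(nrow(rep1$profile_t_tests), 4L)
  expect_identical(nrow(rep1$steatosis_t_tests), 6L)
  expect_true(all(rep1$correlations$n == 60))
  rep2 <- run_study_analysis(rev(coh))
  expect_equal(rep1$regression$slope, rep2$regression$slope)
  expect_equal(rep1$correlations$r, rep2$correlations$r)
  expect_error(run_study_analysis(list()), "empty")
})

test_that("degenerate grouping is flagged as insufficient, not computed", {
  coh <- sample_cohort(cohort_params(
    n = 12, seed = 22,
    profile_mix = c(RP = 1, FP = 0, FTP = 0, PP = 0, indeterminate = 0)))
  rep <- run_study_analysis(coh)
  rp_row <- rep$profile_t_tests[rep$profile_t_tests$group == "RP", ]
  expect_true(rp_row$insufficient)   # no complement group to compare with
  expect_true(is.na(rp_row$p_value))
})

test_that("report serialization writes the documented tables", {
  coh <- sample_cohort(cohort_params(n = 20, seed = 23))
  rep <- run_study_analysis(coh)
  d <- withr::local_tempdir()
  write_stats_report(rep, d)
  expect_true(all(file.exists(file.path(d,
    c("correlations.csv", "partial_correlations.csv", "regression.csv",
      "profile_t_tests.csv", "steatosis_t_tests.csv", "summary.txt")))))
  reg <- utils::read.csv(file.path(d, "regression.csv"))
  expect_equal(reg$slope, rep$regression$slope, tolerance = 1e-9)
})
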