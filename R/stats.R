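# The cohort statistical workflow as deterministic, testable operations:
# normality checks (Lilliefors-corrected KS and Shapiro-Wilk), one-sample
# t confidence intervals, Levene-gated independent-samples t-tests, Pearson
# and partial correlations, simple linear regression, and the Fisher-z
# power analysis for a correlation coefficient.

check_numvec <- function(x, nm, min_n = 1L) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric vector", nm), call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("'%s' needs at least %d observations", nm, min_n),
         call. = FALSE)
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t transform for significance
#' and the determination coefficient `r^2`.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`.
#' @return List of class `"correlation_result"`: `r`, `p_value`, `n`,
#'   `r_squared`, `df`.
#' @export
pearson <- function(x, y) {
  check_numvec(x, "x", 3L); check_numvec(y, "y", 3L)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  n <- length(x)
  r <- stats::cor(x, y)
  df <- n - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, p_value = p, n = n, r_squared = r^2, df = df),
            class = "correlation_result")
}

#' Partial correlation controlling for covariates
#'
#' Correlates the least-squares residuals of `x` and `y` after projecting
#' each on an intercept plus the control columns; the p-value uses
#' `df = n - 2 - ncol(controls)`.  With no controls this reduces exactly to
#' [pearson()].
#'
#' @param x,y Numeric vectors.
#' @param controls Numeric matrix / data frame of control variables (may
#'   have zero columns).
#' @return A `"correlation_result"` as in [pearson()].
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  check_numvec(x, "x", 3L); check_numvec(y, "y", 3L)
  if (is.null(controls)) controls <- matrix(nrow = length(x), ncol = 0)
  controls <- as.matrix(controls)
  storage.mode(controls) <- "double"
  k <- ncol(controls)
  n <- length(x)
  if (length(y) != n || nrow(controls) != n)
    stop("inputs must have equal length", call. = FALSE)
  if (n <= k + 2L)
    stop("need n > #controls + 2 observations", call. = FALSE)
  if (k > 0) {
    z <- cbind(1, controls)
    if (qr(z)$rank < ncol(z))
      stop("collinear control variables", call. = FALSE)
    rx <- stats::lsfit(controls, x)$residuals
    ry <- stats::lsfit(controls, y)$residuals
  } else {
    rx <- x; ry <- y
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined partial correlation: zero residual variance",
         call. = FALSE)
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, p_value = p, n = n, r_squared = r^2, df = df),
            class = "correlation_result")
}

#' One-sample t confidence interval
#'
#' Symmetric t-based confidence interval for a mean.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param level Confidence level in `(0, 1)` (default 0.95).
#' @return Named vector `c(mean, ci_low, ci_high)`.
#' @export
one_sample_ci <- function(values, level = 0.95) {
  check_numvec(values, "values", 2L)
  stopifnot(level > 0, level < 1)
  n <- length(values)
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, n - 1L) * stats::sd(values) / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Levene's test for equality of variances (mean-centered)
#'
#' One-way ANOVA on the absolute deviations from the group means — the
#' classic (mean-centered) Levene statistic used to gate the pooled
#' t-test.
#'
#' @param g1,g2 Numeric vectors, each `n >= 2`.
#' @return List with `statistic` (F), `p_value`, `df1`, `df2`.
#' @export
levene_test <- function(g1, g2) {
  check_numvec(g1, "g1", 2L); check_numvec(g2, "g2", 2L)
  z1 <- abs(g1 - mean(g1)); z2 <- abs(g2 - mean(g2))
  z <- c(z1, z2)
  grp <- rep(c(1L, 2L), c(length(g1), length(g2)))
  n <- length(z); k <- 2L
  zbar <- mean(z)
  ssb <- length(z1) * (mean(z1) - zbar)^2 + length(z2) * (mean(z2) - zbar)^2
  ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  f <- (ssb / (k - 1L)) / (ssw / (n - k))
  list(statistic = f, p_value = stats::pf(f, k - 1L, n - k,
                                          lower.tail = FALSE),
       df1 = k - 1L, df2 = n - k)
}

#' Levene-gated independent-samples t-test
#'
#' Computes Levene's test first; when its p-value exceeds 0.05 the
#' equal-variance (pooled) t-test is used, otherwise Welch's.
#'
#' @param g1,g2 Numeric vectors, each `n >= 2`.
#' @return List of class `"ttest_result"`: `mean_diff` (g1 - g2), `se_diff`,
#'   `t`, `df`, `p_value`, `levene_p`, `equal_var_assumed`.
#' @export
independent_t_test <- function(g1, g2) {
  check_numvec(g1, "g1", 2L); check_numvec(g2, "g2", 2L)
  lev <- levene_test(g1, g2)
  equal_var <- is.finite(lev$p_value) && lev$p_value > 0.05
  ht <- stats::t.test(g1, g2, var.equal = equal_var)
  structure(list(mean_diff = mean(g1) - mean(g2),
                 se_diff = unname(ht$stderr),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, levene_p = lev$p_value,
                 equal_var_assumed = equal_var),
            class = "ttest_result")
}

#' Simple linear regression with a 95% slope interval
#'
#' Ordinary least squares of `y` on `x` with the t-based confidence
#' interval for the slope.
#'
#' @param x,y Numeric vectors, `n >= 3`, `var(x) > 0`.
#' @param level Confidence level (default 0.95).
#' @return List of class `"regression_result"`: `slope`, `intercept`,
#'   `slope_se`, `slope_ci_low`, `slope_ci_high`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y, level = 0.95) {
  check_numvec(x, "x", 3L); check_numvec(y, "y", 3L)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  if (stats::var(x) == 0) stop("zero predictor variance", call. = FALSE)
  n <- length(x)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2]); intercept <- unname(fit$coefficients[1])
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - 2L)
  se <- sqrt(sigma2 / sum((x - mean(x))^2))
  tq <- stats::qt(1 - (1 - level) / 2, n - 2L)
  tval <- if (se > 0) slope / se else Inf * sign(slope)
  p <- if (se > 0) 2 * stats::pt(-abs(tval), n - 2L) else 0
  structure(list(slope = slope, intercept = intercept, slope_se = se,
                 slope_ci_low = slope - tq * se,
                 slope_ci_high = slope + tq * se,
                 p_value = p, n = n),
            class = "regression_result")
}

#' Power of the two-sided Pearson correlation test
#'
#' Fisher-z approximation:
#' \deqn{power = \Phi(\sqrt{n-3}\,\mathrm{atanh}\,\rho - z_{1-\alpha/2})
#'             + \Phi(-\sqrt{n-3}\,\mathrm{atanh}\,\rho - z_{1-\alpha/2}).}
#' Strictly increasing in both `n` and `rho`.
#'
#' @param n Sample size, `>= 4`.
#' @param rho True correlation under the alternative, in `[0, 1)`.
#' @param alpha Two-sided significance level, in `(0, 1)`.
#' @return Power (probability of rejecting the null of zero correlation).
#' @examples
#' power_correlation(100, 0.316, 0.05)   # ~0.90
#' @export
power_correlation <- function(n, rho, alpha = 0.05) {
  stopifnot(length(n) == 1L, n >= 4, is.finite(rho), rho >= 0, rho < 1,
            alpha > 0, alpha < 1)
  zc <- stats::qnorm(1 - alpha / 2)
  shift <- sqrt(n - 3) * atanh(rho)
  stats::pnorm(shift - zc) + stats::pnorm(-shift - zc)
}

#' Minimum detectable correlation at a given power
#'
#' Inverts [power_correlation()] in `rho` by bisection on `(0, 1)` to
#' tolerance `1e-6`.
#'
#' @param n Sample size, `>= 4`.
#' @param power Target power in `(alpha, 1)`.
#' @param alpha Two-sided significance level.
#' @return The smallest `rho` whose test power reaches `power`.
#' @examples
#' min_detectable_correlation(100, 0.90, 0.05)   # ~0.316
#' @export
min_detectable_correlation <- function(n, power, alpha = 0.05) {
  stopifnot(power > 0, power < 1)
  f <- function(r) power_correlation(n, r, alpha) - power
  if (f(0) > 0 || f(1 - 1e-12) < 0)
    stop("no correlation in (0, 1) attains the requested power",
         call. = FALSE)
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Normality checks (Lilliefors KS and Shapiro-Wilk)
#'
#' The one-sample KS test is run against a normal with estimated mean and
#' SD, with the Lilliefors correction for the estimated parameters (the
#' default behaviour of the SPSS normality table); Shapiro-Wilk is the
#' standard test.  Large p-values in both are read as no evidence against
#' normality.
#'
#' @param values Numeric vector (`n >= 4` for the Lilliefors p
#'   approximation, `n >= 3` for Shapiro-Wilk), non-constant.
#' @return Named vector `c(ks_p, sw_p)`.
#' @export
normality_tests <- function(values) {
  check_numvec(values, "values", 4L)
  if (stats::sd(values) == 0)
    stop("degenerate input: constant vector", call. = FALSE)
  c(ks_p = lilliefors_p(values), sw_p = stats::shapiro.test(values)$p.value)
}

# Lilliefors test p-value via the Dallal-Wilkinson (1986) approximation as
# modified by Stephens; mirrors the standard implementation used by SPSS
# and by nortest::lillie.test.
lilliefors_p <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  dplus <- max(seq_len(n) / n - p)
  dminus <- max(p - (seq_len(n) - 1) / n)
  k <- max(dplus, dminus)
  if (n <= 100) { kd <- k; nd <- n } else { kd <- k * (n / 100)^0.49; nd <- 100 }
  pvalue <- exp(-7.01256 * kd^2 * (nd + 2.78019) + 2.99587 * kd *
                  sqrt(nd + 2.78019) - 0.122119 + 0.974598 / sqrt(nd) +
                  1.67997 / nd)
  if (pvalue > 0.1) {
    kk <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * k
    if (kk <= 0.302) pvalue <- 1
    else if (kk <= 0.5)
      pvalue <- 2.76773 - 19.828315 * kk + 80.709644 * kk^2 -
        138.55152 * kk^3 + 81.218052 * kk^4
    else if (kk <= 0.9)
      pvalue <- -4.901232 + 40.662806 * kk - 97.490286 * kk^2 +
        94.029866 * kk^3 - 32.355711 * kk^4
    else if (kk <= 1.31)
      pvalue <- 6.198765 - 19.558097 * kk + 23.186922 * kk^2 -
        12.234627 * kk^3 + 2.423045 * kk^4
    else pvalue <- 0
  }
  min(max(pvalue, 0), 1)
}

#' Run the full cohort analysis
#'
#' Mirrors the study's reporting structure on a classified cohort:
#' \itemize{
#'   \item Pearson correlations of \{WC, BMI, K2, InfArc, Area2, Vlow\}
#'     with \{RHD, LHD, SHD\};
#'   \item partial correlations of \{InfArc, Area2, Vlow\} with SHD
#'     controlling sex, height and weight;
#'   \item the simple regression SHD ~ InfArc;
#'   \item independent t-tests of SHD between each profile type and its
#'     complement, and of RHD/LHD/SHD between A/B steatosic and
#'     non-steatosic abdomens.
#' }
#' Cells with insufficient group sizes are flagged rather than computed.
#'
#' @param cohort List of `"patient_record"` objects.
#' @return Object of class `"cohort_stats_report"` with data-frame
#'   components `correlations`, `partial_correlations`, `regression`,
#'   `profile_t_tests`, `steatosis_t_tests`, and the cohort size `n`.
#' @export
run_study_analysis <- function(cohort) {
  if (length(cohort) == 0) stop("empty cohort", call. = FALSE)
  tab <- patients_to_table(cohort)
  num <- function(col) as.numeric(tab[[col]])
  predictors <- c(WC = "wc", BMI = "bmi", K2 = "k2", InfArc = "inf_arc",
                  Area2 = "area2", Vlow = "vlow")
  outcomes <- c(RHD = "rhd", LHD = "lhd", SHD = "shd")
  corr <- do.call(rbind, lapply(names(predictors), function(pn) {
    do.call(rbind, lapply(names(outcomes), function(on) {
      x <- num(predictors[[pn]]); y <- num(outcomes[[on]])
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(data.frame(predictor = pn, outcome = on, r = NA, r_squared = NA,
                          p_value = NA, n = sum(ok), insufficient = TRUE))
      ct <- pearson(x[ok], y[ok])
      data.frame(predictor = pn, outcome = on, r = ct$r,
                 r_squared = ct$r_squared, p_value = ct$p_value, n = ct$n,
                 insufficient = FALSE)
    }))
  }))
  ctrl <- cbind(sex = as.numeric(tab$sex == "M"), height = num("height"),
                weight = num("weight"))
  partial <- do.call(rbind, lapply(c(InfArc = "inf_arc", Area2 = "area2",
                                     Vlow = "vlow"), function(col) {
    x <- num(col); y <- num("shd")
    ok <- is.finite(x) & is.finite(y) & stats::complete.cases(ctrl)
    if (sum(ok) < 6)
      return(data.frame(predictor = col, r = NA, p_value = NA, n = sum(ok),
                        insufficient = TRUE))
    pc <- partial_correlation(x[ok], y[ok], ctrl[ok, , drop = FALSE])
    data.frame(predictor = col, r = pc$r, p_value = pc$p_value, n = pc$n,
               insufficient = FALSE)
  }))
  partial$predictor <- c("InfArc", "Area2", "Vlow")
  ok <- is.finite(num("inf_arc")) & is.finite(num("shd"))
  reg <- linear_regression(num("inf_arc")[ok], num("shd")[ok])
  ttest_row <- function(label, outcome_col, in_grp) {
    y <- num(outcome_col)
    g1 <- y[in_grp & is.finite(y)]; g2 <- y[!in_grp & is.finite(y)]
    if (length(g1) < 2 || length(g2) < 2)
      return(data.frame(group = label, outcome = toupper(outcome_col),
                        mean_diff = NA, p_value = NA, levene_p = NA,
                        equal_var_assumed = NA,
                        n1 = length(g1), n2 = length(g2),
                        insufficient = TRUE))
    tt <- independent_t_test(g1, g2)
    data.frame(group = label, outcome = toupper(outcome_col),
               mean_diff = tt$mean_diff, p_value = tt$p_value,
               levene_p = tt$levene_p,
               equal_var_assumed = tt$equal_var_assumed,
               n1 = length(g1), n2 = length(g2), insufficient = FALSE)
  }
  prof <- do.call(rbind, list(
    ttest_row("RP", "shd", tab$criterion1 == "RP"),
    ttest_row("FP", "shd", tab$criterion1 == "FP"),
    ttest_row("FTP", "shd", tab$criterion2 == "FTP"),
    ttest_row("PP", "shd", tab$criterion2 == "PP")))
  ste <- do.call(rbind, unlist(lapply(c("type_a", "type_b"), function(ty) {
    lapply(c("rhd", "lhd", "shd"), function(oc) {
      in_st <- tab[[ty]] == "steatosic"
      in_non <- tab[[ty]] == "non_steatosic"
      y <- num(oc)
      g1 <- y[in_st & is.finite(y)]; g2 <- y[in_non & is.finite(y)]
      label <- if (ty == "type_a") "A" else "B"
      if (length(g1) < 2 || length(g2) < 2)
        return(data.frame(group = label, outcome = toupper(oc),
                          mean_diff = NA, p_value = NA, levene_p = NA,
                          equal_var_assumed = NA, n1 = length(g1),
                          n2 = length(g2), insufficient = TRUE))
      tt <- independent_t_test(g1, g2)
      data.frame(group = label, outcome = toupper(oc),
                 mean_diff = tt$mean_diff, p_value = tt$p_value,
                 levene_p = tt$levene_p,
                 equal_var_assumed = tt$equal_var_assumed,
                 n1 = length(g1), n2 = length(g2), insufficient = FALSE)
    })
  }), recursive = FALSE))
  structure(list(correlations = corr, partial_correlations = partial,
                 regression = reg, profile_t_tests = prof,
                 steatosis_t_tests = ste, n = length(cohort)),
            class = "cohort_stats_report")
}

#' Serialize a cohort report to CSV tables
#'
#' Writes `correlations.csv`, `partial_correlations.csv`,
#' `regression.csv`, `profile_t_tests.csv`, `steatosis_t_tests.csv` and a
#' short `summary.txt` into a directory.
#'
#' @param report A `"cohort_stats_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stats_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$partial_correlations,
                   file.path(dir, "partial_correlations.csv"),
                   row.names = FALSE)
  reg <- report$regression
  utils::write.csv(data.frame(slope = reg$slope, intercept = reg$intercept,
                              slope_ci_low = reg$slope_ci_low,
                              slope_ci_high = reg$slope_ci_high,
                              p_value = reg$p_value, n = reg$n),
                   file.path(dir, "regression.csv"), row.names = FALSE)
  utils::write.csv(report$profile_t_tests,
                   file.path(dir, "profile_t_tests.csv"), row.names = FALSE)
  utils::write.csv(report$steatosis_t_tests,
                   file.path(dir, "steatosis_t_tests.csv"), row.names = FALSE)
  writeLines(c(sprintf("cohort n = %d", report$n),
               sprintf("SHD ~ InfArc slope = %.4f (95%% CI %.4f..%.4f), p = %.3g",
                       reg$slope, reg$slope_ci_low, reg$slope_ci_high,
                       reg$p_value)),
             file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.cohort_stats_report <- function(x, ...) {
  cat(sprintf("Cohort statistics report (n = %d)\n\n", x$n))
  cat("Correlations with liver diameters:\n")
  print(x$correlations, row.names = FALSE)
  cat("\nPartial correlations with SHD (controls: sex, height, weight):\n")
  print(x$partial_correlations, row.names = FALSE)
  cat(sprintf("\nRegression SHD ~ InfArc: slope %.4f (95%% CI %.4f..%.4f), p = %.3g\n",
              x$regression$slope, x$regression$slope_ci_low,
              x$regression$slope_ci_high, x$regression$p_value))
  invisible(x)
}
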