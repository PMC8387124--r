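#' Log-log model selection for the age trajectory of mortality
#'
#' The decline of child mortality with age is assessed in the log-log
#' scale in three stages:
#'
#' 1. **Curvature test** — ordinary least squares of ln(mu) on ln(x) and
#'    its square; linearity is retained when the quadratic coefficient is
#'    not significant at alpha = 0.05.
#' 2. **Two-parameter linear fit** — ln(mu) = ln(mu1) + gamma * ln(x),
#'    estimated by OLS, with a t-based confidence interval for the slope
#'    gamma and the adjusted coefficient of determination.
#' 3. **Nested inverse-proportion test** — the one-parameter law
#'    mu(x) = mu1 / x fixes gamma = -1 and is nested in the linear model;
#'    H0 "the two-parameter model fits no better" is examined with a
#'    standard F-test on (1, n - 2) degrees of freedom. The coefficient of
#'    determination attained by the inverse model (Rb^2) is reported
#'    alongside.
#'
#' All decisions use alpha = 0.05.
#'
#' @name trajectory
NULL

.EPS_RSS <- 1e-12

#' Extract log-log points from a trajectory
#'
#' Natural logs of category midpoints and rates for the categories whose
#' midpoints fall inside `age_range`. Every such category must have at
#' least one pooled death: a zero rate has no logarithm, and the remedy is
#' wider Halley pooling, not silent dropping.
#'
#' @param atm An `atm` object.
#' @param age_range Length-2 numeric `(lower, upper)` in years; default the
#'   first ten years of life.
#' @return A data frame of class `"loglog_points"` with columns `label`,
#'   `x`, `lnx`, `lnmu`, ordered by age.
#' @export
loglog_points <- function(atm, age_range = c(0, 10)) {
  rows <- atm[atm$x > age_range[1] & atm$x < age_range[2], , drop = FALSE]
  bad <- rows$label[!rows$usable]
  if (length(bad)) {
    stop("zero-death categories in the fitting range (pool more data): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(rows) < 3L) {
    stop("need at least 3 usable age categories in the range, got ",
         nrow(rows), call. = FALSE)
  }
  out <- data.frame(label = rows$label, x = rows$x, lnx = log(rows$x),
                    lnmu = log(rows$rate), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("loglog_points", "data.frame")
  out
}

#' Test for curvature in the log-log scale
#'
#' OLS of ln(mu) on \{1, ln(x), ln(x)^2\}; the two-sided t-test of the
#' quadratic coefficient decides at alpha = 0.05 whether the trajectory is
#' linear in log-log coordinates.
#'
#' @param points A `loglog_points` data frame with at least 4 points.
#' @return List with `quad_coef`, `p_quad`, `p_linear`, `rejected`
#'   (curvature detected) and the underlying `lm` fit.
#' @export
test_curvature <- function(points) {
  n <- nrow(points)
  if (n < 4L) stop("curvature test needs at least 4 points (got ", n, ")",
                   call. = FALSE)
  if (length(unique(points$lnx)) < 3L) {
    stop("abscissae are collinear: quadratic model is rank-deficient",
         call. = FALSE)
  }
  fit <- stats::lm(lnmu ~ lnx + I(lnx^2), data = points)
  # summary.lm warns on exact fits; the zero-RSS case is guarded below
  cf <- suppressWarnings(summary(fit))$coefficients
  rss <- sum(stats::resid(fit)^2)
  p_quad <- if (rss < .EPS_RSS && abs(cf["I(lnx^2)", 1]) < 1e-10) 1
            else cf["I(lnx^2)", 4]
  list(quad_coef = unname(cf["I(lnx^2)", 1]),
       p_quad = unname(p_quad),
       p_linear = unname(cf["lnx", 4]),
       rejected = unname(p_quad) < 0.05,
       fit = fit)
}

#' Fit the two-parameter log-log line
#'
#' Ordinary least squares of ln(mu) on ln(x). The intercept is ln(mu1),
#' the model rate at age 1 year; the slope gamma measures the speed of the
#' mortality decline, with gamma = -1 the inverse proportion.
#'
#' @param points A `loglog_points` data frame with at least 3 points.
#' @param ci_level Confidence level for the slope interval (t-based),
#'   default 0.95.
#' @param scale Reporting scale for `mu1_level`: rate per `scale`
#'   person-years, default 1000. The scale shifts only the reported level,
#'   never gamma, R^2 or any p-value.
#' @return An object of class `"loglog_fit"`.
#' @export
fit_loglog <- function(points, ci_level = 0.95, scale = 1000) {
  n <- nrow(points)
  if (n < 3L) stop("log-log fit needs at least 3 points (got ", n, ")",
                   call. = FALSE)
  if (length(unique(points$lnx)) < 2L) {
    stop("all abscissae identical: slope is undefined", call. = FALSE)
  }
  fit <- stats::lm(lnmu ~ lnx, data = points)
  # summary.lm warns on exact collinear data; perfect fits are legitimate
  # inputs here (they arise from noise-free generator profiles)
  cf <- suppressWarnings(summary(fit))$coefficients
  gamma <- unname(cf["lnx", 1]); se_gamma <- unname(cf["lnx", 2])
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = n - 2)
  res <- stats::resid(fit)
  rss <- sum(res^2)
  tss <- sum((points$lnmu - mean(points$lnmu))^2)
  r2 <- 1 - rss / tss
  structure(list(
    n = n, gamma = gamma, ln_mu1 = unname(cf["(Intercept)", 1]),
    se_gamma = se_gamma, se_ln_mu1 = unname(cf["(Intercept)", 2]),
    ci_level = ci_level,
    ci_lower = gamma - tcrit * se_gamma, ci_upper = gamma + tcrit * se_gamma,
    scale = scale, mu1_level = scale * exp(unname(cf["(Intercept)", 1])),
    r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    rss = rss, tss = tss, residuals = unname(res),
    fitted = unname(stats::fitted(fit)), points = points, lm = fit
  ), class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("Log-log linear fit on %d age categories\n", x$n))
  cat(sprintf("  slope gamma = %.4f  (%d%% CI %.4f to %.4f)\n", x$gamma,
              round(100 * x$ci_level), x$ci_lower, x$ci_upper))
  cat(sprintf("  level mu1   = %.4g per %g person-years at age 1 year\n",
              x$mu1_level, x$scale))
  cat(sprintf("  adjusted R2 = %.4f\n", x$r2_adj))
  invisible(x)
}

#' Nested test of the inverse-proportion law
#'
#' The inverse proportion mu(x) = mu1 / x is the linear model with the
#' slope pinned at -1; its single parameter has the least-squares solution
#' ln(mu1) = mean(ln mu_i + ln x_i). H0: gamma = -1 (equivalently: the
#' two-parameter line fits no better than the inverse proportion) is
#' tested with F = (RSS_inverse - RSS_linear) / (RSS_linear / (n - 2)) on
#' (1, n - 2) degrees of freedom. Rb^2 = 1 - RSS_inverse / TSS is the
#' coefficient of determination achieved by the one-parameter law.
#'
#' A perfect linear fit (RSS_linear = 0) is guarded: the test returns
#' F = 0 and p = 1 when the inverse model is also exact, and p = 0 when it
#' is not.
#'
#' @param points A `loglog_points` data frame.
#' @param fit The [fit_loglog()] result on the same points (computed if
#'   missing).
#' @return List of class `"inverse_test"` with `rss_linear`,
#'   `rss_inverse`, `F_stat`, `p_value`, `rb2`, `ln_mu1`, `mu1_level`
#'   (inverse-model level on the fit's reporting scale) and `rejected`.
#' @export
test_inverse <- function(points, fit = fit_loglog(points)) {
  n <- nrow(points)
  if (n < 3L) stop("inverse test needs at least 3 points", call. = FALSE)
  a <- mean(points$lnmu + points$lnx)        # LS estimate of ln(mu1)
  res_inv <- points$lnmu - (a - points$lnx)
  rss_inv <- sum(res_inv^2)
  rss_lin <- fit$rss
  if (rss_lin < .EPS_RSS) {
    F_stat <- if (rss_inv - rss_lin < .EPS_RSS) 0 else Inf
    p <- if (is.infinite(F_stat)) 0 else 1
  } else {
    F_stat <- (rss_inv - rss_lin) / (rss_lin / (n - 2))
    p <- stats::pf(F_stat, 1, n - 2, lower.tail = FALSE)
  }
  rb2 <- if (rss_inv < .EPS_RSS) 1 else 1 - rss_inv / fit$tss
  structure(list(rss_linear = rss_lin, rss_inverse = rss_inv,
                 F_stat = F_stat, p_value = p, rb2 = rb2,
                 ln_mu1 = a, mu1_level = fit$scale * exp(a),
                 residuals_inverse = res_inv,
                 rejected = p < 0.05),
            class = "inverse_test")
}

#' @export
print.inverse_test <- function(x, ...) {
  cat(sprintf("Inverse-proportion test: F = %.4g, p = %.4g (%s at alpha = 0.05)\n",
              x$F_stat, x$p_value,
              if (x$rejected) "rejected" else "not rejected"))
  cat(sprintf("  Rb2 = %.4f, inverse-model level mu1 = %.4g\n", x$rb2, x$mu1_level))
  invisible(x)
}

#' Predicted rate under a fitted inverse-proportion model
#'
#' @param x Age(s) in years, > 0.
#' @param inverse_test An `"inverse_test"` result (or a number taken as
#'   mu1 on the per-person-year scale).
#' @return Rate per person-year at each age.
#' @export
inverse_hazard <- function(x, inverse_test) {
  mu1 <- if (inherits(inverse_test, "inverse_test")) exp(inverse_test$ln_mu1)
         else inverse_test
  stopifnot(all(x > 0))
  mu1 / x
}

#' Test for age independence of the rate
#'
#' t-test of H0: gamma = 0 in the two-parameter log-log fit; a trajectory
#' whose slope does not differ from zero is age-independent (the pattern
#' seen for neoplasm mortality after the first year of life).
#'
#' @param points A `loglog_points` data frame.
#' @param ci_level Passed to [fit_loglog()].
#' @return List with `slope`, `se`, `t_stat`, `p_value`, `rejected`.
#' @export
test_zero_slope <- function(points, ci_level = 0.95) {
  fit <- fit_loglog(points, ci_level = ci_level)
  if (fit$se_gamma < 1e-300) {
    p <- if (abs(fit$gamma) < 1e-10) 1 else 0
    t_stat <- if (p == 1) 0 else Inf
  } else {
    t_stat <- fit$gamma / fit$se_gamma
    p <- 2 * stats::pt(abs(t_stat), df = fit$n - 2, lower.tail = FALSE)
  }
  list(slope = fit$gamma, se = fit$se_gamma, t_stat = t_stat, p_value = p,
       rejected = p < 0.05)
}

# All permutations of 1..n as an (n! x n) matrix; used for the exact
# residual-independence test at small n.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

#' Test whether residuals are age-independent
#'
#' Spearman rank correlation between model residuals and ln(x). With 8 or
#' fewer points the p-value is exact, from the full permutation
#' distribution of the rank correlation; otherwise the asymptotic t
#' approximation is used. Residuals that are all (numerically) zero give
#' p = 1.
#'
#' @param points A `loglog_points` data frame with at least 4 points.
#' @param model `"linear"` (residuals of the two-parameter fit) or
#'   `"inverse"` (residuals of the one-parameter inverse model).
#' @return List with `rho`, `p_value`, `method`, `rejected`.
#' @export
test_residual_independence <- function(points, model = c("linear", "inverse")) {
  model <- match.arg(model)
  n <- nrow(points)
  if (n < 4L) stop("residual-independence test needs at least 4 points",
                   call. = FALSE)
  res <- if (model == "linear") fit_loglog(points)$residuals
         else test_inverse(points)$residuals_inverse
  if (all(abs(res) < 1e-10)) {
    return(list(rho = 0, p_value = 1, method = "degenerate (all residuals zero)",
                rejected = FALSE))
  }
  rr <- rank(res); rx <- rank(points$lnx)
  rho <- stats::cor(rr, rx)
  if (n <= 8L) {
    perms <- all_perms(n)
    # vectorised rank correlation over all permutations: with rx centred,
    # cor(rr[p], rx) = sum(rr[p] * rxc) / sqrt(ss_rr * ss_rx)
    rxc <- rx - mean(rx)
    rhos <- as.vector(matrix(rr[perms], nrow = nrow(perms)) %*% rxc) /
      sqrt(sum((rr - mean(rr))^2) * sum(rxc^2))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    ct <- suppressWarnings(stats::cor.test(res, points$lnx, method = "spearman"))
    p <- ct$p.value
    method <- "asymptotic Spearman"
  }
  list(rho = rho, p_value = p, method = method, rejected = p < 0.05)
}

#' Locate the mortality minimum along a trajectory
#'
#' The age category with the lowest pooled rate, ties broken toward the
#' younger category. In childhood trajectories the minimum typically falls
#' in the 5-9 years band, occasionally in 10-14 years.
#'
#' @param atm An `atm` object with at least 2 categories with positive
#'   exposure.
#' @return The minimising row of the trajectory.
#' @export
find_minimum <- function(atm) {
  ok <- atm$person_years > 0
  if (sum(ok) < 2L) stop("need at least 2 categories with positive exposure",
                         call. = FALSE)
  if (all(atm$rate[ok] == 0)) {
    stop("all rates are zero: mortality minimum is undefined", call. = FALSE)
  }
  rows <- atm[ok, , drop = FALSE]
  rows[which.min(rows$rate), , drop = FALSE]   # first minimum = youngest
}

#' One report row for a fitted population
#'
#' Runs the linear fit and the nested inverse-proportion test over
#' `age_range` and returns the standard reporting columns: slope with its
#' confidence bounds, level mu1, adjusted R^2, Rb^2 and the inverse-test
#' p-value.
#'
#' @param atm An `atm` object.
#' @param age_range Fitting range in years, default `c(0, 10)`.
#' @param ci_level,scale Passed to [fit_loglog()].
#' @param size Population size to report (e.g. the mean number of living
#'   persons); `NA` if unknown.
#' @param years Text describing the calendar period.
#' @return A one-row data frame with columns `population`, `years`,
#'   `size`, `slope`, `lower`, `upper`, `level_mu1`, `r2_adj`, `rb2`,
#'   `p_inverse`.
#' @export
report_row <- function(atm, age_range = c(0, 10), ci_level = 0.95,
                       scale = 1000, size = NA_real_, years = "x") {
  pts <- loglog_points(atm, age_range)
  fit <- fit_loglog(pts, ci_level = ci_level, scale = scale)
  inv <- test_inverse(pts, fit)
  data.frame(population = attr(atm, "population"), years = years, size = size,
             slope = fit$gamma, lower = fit$ci_lower, upper = fit$ci_upper,
             level_mu1 = fit$mu1_level, r2_adj = fit$r2_adj, rb2 = inv$rb2,
             p_inverse = inv$p_value, stringsAsFactors = FALSE)
}

#' Multi-population trajectory report
#'
#' Aggregates and fits each named population and stacks the report rows.
#'
#' @param deaths,pop Input tables.
#' @param populations Named list of presets; each preset is a list with
#'   `countries` (character vector) and `years` (vector or named
#'   per-country list), optionally `size` and `period`.
#' @param group,grid,age_range,ci_level,scale As elsewhere.
#' @return A data frame with one [report_row()] per preset.
#' @export
trajectory_report <- function(deaths, pop, populations, group = cg_total(),
                              grid = standard_age_grid(10),
                              age_range = c(0, 10), ci_level = 0.95,
                              scale = 1000) {
  rows <- lapply(names(populations), function(nm) {
    ps <- populations[[nm]]
    atm <- aggregate_atm(deaths, pop, ps$countries, ps$years, group = group,
                         grid = grid, population_name = nm)
    report_row(atm, age_range = age_range, ci_level = ci_level, scale = scale,
               size = if (is.null(ps$size)) NA_real_ else ps$size,
               years = if (is.null(ps$period)) "x" else ps$period)
  })
  do.call(rbind, rows)
}

#' Render a report at the conventional printed precision
#'
#' Slopes to 3 decimals, interval bounds to 2, the level to 1, the
#' coefficients of determination to 4 and p-values to 2.
#'
#' @param report Output of [trajectory_report()] or [report_row()].
#' @return A data frame of formatted character columns.
#' @export
format_report <- function(report) {
  data.frame(population = report$population, years = report$years,
             size = ifelse(is.na(report$size), "x",
                           format(report$size, big.mark = ",", trim = TRUE)),
             slope = sprintf("%.3f", report$slope),
             lower = sprintf("%.2f", report$lower),
             upper = sprintf("%.2f", report$upper),
             level_mu1 = sprintf("%.1f", report$level_mu1),
             r2_adj = sprintf("%.4f", report$r2_adj),
             rb2 = sprintf("%.4f", report$rb2),
             p_inverse = sprintf("%.2f", report$p_inverse),
             stringsAsFactors = FALSE)
}
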