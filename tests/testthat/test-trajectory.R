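make_atm <- function(rates, grid = standard_age_grid(10)) {
  structure(data.frame(label = grid$label, lower = grid$lower,
                       upper = grid$upper, band = grid$band,
                       x = midpoint(grid), deaths = ifelse(rates > 0, 1, 0),
                       person_years = 1e6, rate = rates,
                       usable = rates > 0, stringsAsFactors = FALSE),
            class = c("atm", "data.frame"),
            population = "manual", cause_group = "TOTAL")
}

test_that("log-log extraction keeps the six childhood categories", {
  g <- standard_age_grid(15)
  atm <- make_atm(0.05 / midpoint(g), g)
  pts <- loglog_points(atm, c(0, 10))
  expect_equal(nrow(pts), 6L)
  expect_equal(pts$lnx, log(midpoint(g))[1:6])

  atm$usable[3] <- FALSE; atm$deaths[3] <- 0
  expect_error(loglog_points(atm, c(0, 10)), "7-27 days")
  expect_error(loglog_points(make_atm(0.05 / midpoint(g), g), c(4, 9)),
               "at least 3")
})

test_that("exact inverse data give a perfect slope -1 line", {
  pts <- points_from_rates(midpoint(standard_age_grid(10)),
                           0.1 / midpoint(standard_age_grid(10)))
  fit <- fit_loglog(pts, scale = 1)
  expect_equal(fit$gamma, -1)
  expect_equal(fit$r2_adj, 1)
  expect_equal(fit$mu1_level, 0.1)
  expect_equal(sum(fit$residuals), 0)
  expect_true(fit$ci_lower < fit$gamma && fit$gamma < fit$ci_upper)
})

test_that("three hand-picked collinear points are fitted exactly", {
  pts <- points_from_rates(c(1, 2, 4), c(8, 4, 2))
  fit <- fit_loglog(pts, scale = 1)
  expect_equal(fit$gamma, -1)
  expect_equal(fit$ln_mu1, log(8))
})

test_that("OLS estimates match an independent normal-equations oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    x <- sort(exp(stats::runif(n, -6, 2.5)))
    mu <- exp(2 - stats::runif(1, 0.5, 1.5) * log(x) + stats::rnorm(n, 0, 0.1))
    pts <- points_from_rates(x, mu)
    fit <- fit_loglog(pts)
    orc <- ols_oracle(cbind(1, log(x)), log(mu))
    expect_equal(fit$ln_mu1, orc$beta[1], tolerance = 1e-10)
    expect_equal(fit$gamma, orc$beta[2], tolerance = 1e-10)
    expect_equal(fit$rss, orc$rss, tolerance = 1e-10)
  }
})

test_that("the F statistic equals the squared t statistic for gamma = -1", {
  set.seed(7)
  for (rep in 1:10) {
    x <- midpoint(standard_age_grid(10))
    mu <- exp(-3 - 0.9 * log(x) + stats::rnorm(6, 0, 0.05))
    pts <- points_from_rates(x, mu)
    fit <- fit_loglog(pts)
    inv <- test_inverse(pts, fit)
    t2 <- ((fit$gamma - (-1)) / fit$se_gamma)^2
    expect_equal(inv$F_stat, t2, tolerance = 1e-10)
    # and the inverse model's RSS matches the constrained normal equations
    a <- mean(pts$lnmu + pts$lnx)
    expect_equal(inv$rss_inverse, sum((pts$lnmu - a + pts$lnx)^2),
                 tolerance = 1e-12)
    expect_gte(inv$rss_inverse, inv$rss_linear)
  }
})

test_that("the nested test is guarded on perfect fits", {
  pts <- points_from_rates(c(1, 2, 4, 8), 5 / c(1, 2, 4, 8))
  inv <- test_inverse(pts)
  expect_equal(inv$F_stat, 0)
  expect_equal(inv$p_value, 1)
  expect_equal(inv$rb2, 1)
  # perfect line with slope != -1: linear RSS 0, inverse RSS > 0
  pts2 <- points_from_rates(c(1, 2, 4, 8), 5 * c(1, 2, 4, 8)^-0.5)
  inv2 <- test_inverse(pts2)
  expect_equal(inv2$p_value, 0)
  expect_true(is.infinite(inv2$F_stat))
})

test_that("curvature is detected when present and not invented when absent", {
  x <- midpoint(standard_age_grid(10))
  # exact line: no curvature
  lin <- test_curvature(points_from_rates(x, exp(1 - log(x))))
  expect_false(lin$rejected)
  expect_equal(lin$quad_coef, 0, tolerance = 1e-8)

  # strong quadratic signal over tiny noise
  set.seed(1)
  lnmu <- 1 - log(x) - 0.5 * log(x)^2 + stats::rnorm(6, 0, 0.01)
  curved <- test_curvature(points_from_rates(x, exp(lnmu)))
  expect_true(curved$rejected)
  # coefficient agrees with the closed-form normal equations
  orc <- ols_oracle(cbind(1, log(x), log(x)^2), lnmu)
  expect_equal(curved$quad_coef, orc$beta[3], tolerance = 1e-10)

  expect_error(test_curvature(points_from_rates(x[1:3], (1 / x)[1:3])),
               "at least 4")
})

test_that("the zero-slope test separates flat from declining trajectories", {
  x <- midpoint(standard_age_grid(10))
  set.seed(2)
  flat <- test_zero_slope(points_from_rates(x, exp(stats::rnorm(6, -7, 0.02))))
  expect_false(flat$rejected)
  declining <- test_zero_slope(points_from_rates(x, 0.1 / x))
  expect_true(declining$rejected)
})

test_that("neoplasm-like trajectories are age-independent after infancy", {
  # under the age-independent truth the zero-slope test should retain H0
  # in at least 90% of replicates
  reject <- logical(100)
  for (i in seq_len(100)) {
    spec <- tiny_spec(profile_neoplasm(5e-4, 2e-4), cause = "II",
                      seed = 1000L + i,
                      countries = list(list(name = "Alpha", years = 2000:2004,
                                            pop_under1 = 1e6, pop_band = 1e6)),
                      grid = standard_age_grid(15))
    ds <- generate_dataset(spec)
    atm <- aggregate_atm(ds$deaths, ds$population, "Alpha", 2000:2004,
                         grid = standard_age_grid(15))
    pts <- loglog_points(atm, c(1, 15))
    reject[i] <- test_zero_slope(pts)$rejected
  }
  expect_lte(mean(reject), 0.10)
})

test_that("residual-independence test is exact, guarded, and powered", {
  x <- midpoint(standard_age_grid(10))
  # perfect inverse fit: all residuals zero
  exact <- test_residual_independence(points_from_rates(x, 2 / x), "inverse")
  expect_equal(exact$p_value, 1)

  # inverse-model residuals from a true slope -0.7 trend strongly with age
  set.seed(3)
  pts <- points_from_rates(x, exp(-4 - 0.7 * log(x) + stats::rnorm(6, 0, 0.005)))
  trended <- test_residual_independence(pts, "inverse")
  expect_lt(trended$p_value, 0.05)

  # the exact permutation p agrees with a random-permutation estimate
  res <- test_inverse(pts)$residuals_inverse
  rr <- rank(res); rx <- rank(log(x))
  set.seed(4)
  rhos <- replicate(10000, stats::cor(rr[sample(6)], rx))
  p_mc <- mean(abs(rhos) >= abs(stats::cor(rr, rx)) - 1e-12)
  expect_equal(trended$p_value, p_mc, tolerance = 0.01)

  expect_error(test_residual_independence(points_from_rates(x[1:3], 1 / x[1:3])),
               "at least 4")
})

test_that("residual-independence test holds its size on null residuals", {
  x <- midpoint(standard_age_grid(10))
  set.seed(5)
  rej <- replicate(500, {
    pts <- points_from_rates(x, exp(-5 - log(x) + stats::rnorm(6, 0, 0.05)))
    c(inverse = test_residual_independence(pts, "inverse")$rejected,
      linear = test_residual_independence(pts, "linear")$rejected)
  })
  # inverse-model residuals under an inverse truth: near-nominal size
  # (the exact permutation distribution at n = 6 is discrete, so the
  # attainable size sits below 5%)
  expect_gt(mean(rej["inverse", ]), 0.01)
  expect_lt(mean(rej["inverse", ]), 0.08)
  # two-parameter OLS residuals are orthogonal to ln x by construction,
  # so this variant can only be conservative, never anticonservative
  expect_lte(mean(rej["linear", ]), 0.05)
})

test_that("the mortality minimum is located with ties broken young", {
  g <- standard_age_grid(15)
  dec <- make_atm(0.1 / midpoint(g), g)
  expect_equal(find_minimum(dec)$label, "10-14 years")

  # inverse decline up to the 5-10 band, rising afterwards
  r <- 0.1 / midpoint(g); r[g$lower >= 10] <- r[g$label == "5-9 years"] * 3
  expect_equal(find_minimum(make_atm(r, g))$label, "5-9 years")

  tied <- make_atm(c(5, 4, 3, 2, 1, 1, 2) / 100, g)
  expect_equal(find_minimum(tied)$label, "1-4 years")

  allzero <- make_atm(rep(0, 7), g)
  allzero$usable <- FALSE
  expect_error(find_minimum(allzero), "all rates are zero")
})

test_that("p-values fall as the true slope moves away from -1", {
  x <- midpoint(standard_age_grid(10))
  med_p <- sapply(c(-1, -0.9, -0.8), function(g) {
    set.seed(6)
    stats::median(replicate(200, {
      pts <- points_from_rates(x, exp(-4 + g * log(x) + stats::rnorm(6, 0, 0.02)))
      test_inverse(pts)$p_value
    }))
  })
  expect_true(all(diff(med_p) < 0))
})

test_that("the slope and level are recovered as exposures grow", {
  c0 <- 0.003
  err <- sapply(c(1, 10, 100), function(mult) {
    spec <- tiny_spec(profile_inverse(c0), seed = 31L,
                      countries = list(list(name = "Alpha", years = 2000:2001,
                                            pop_under1 = 2e5 * mult,
                                            pop_band = 2e5 * mult)))
    ds <- generate_dataset(spec)
    atm <- aggregate_atm(ds$deaths, ds$population, "Alpha", 2000:2001)
    fit <- fit_loglog(loglog_points(atm, c(0, 10)), scale = 1)
    c(abs(fit$gamma + 1), abs(exp(fit$ln_mu1) - c0) / c0)
  })
  expect_lt(err[1, 3], err[1, 1] + 0.01)
  expect_lt(err[1, 3], 0.02)       # slope within 2% at the largest exposure
  expect_lt(err[2, 3], 0.05)       # level within 5%
})

test_that("report rows carry the fit verbatim at the printed precision", {
  spec <- tiny_spec(profile_inverse(0.002), seed = 9L)
  ds <- generate_dataset(spec)
  atm <- aggregate_atm(ds$deaths, ds$population, "Alpha", 2000:2001,
                       population_name = "Alpha")
  row <- report_row(atm, size = 123456)
  pts <- loglog_points(atm, c(0, 10))
  fit <- fit_loglog(pts)
  inv <- test_inverse(pts, fit)
  expect_equal(row$slope, fit$gamma)
  expect_equal(row$level_mu1, fit$mu1_level)
  expect_equal(row$rb2, inv$rb2)
  expect_equal(row$p_inverse, inv$p_value)

  rep2 <- trajectory_report(ds$deaths, ds$population,
                            list(Alpha = list(countries = "Alpha",
                                              years = 2000:2001,
                                              size = 123456)))
  expect_equal(rep2$slope, row$slope)

  fmt <- format_report(row)
  expect_match(fmt$slope, "^-?[0-9]+\\.[0-9]{3}$")
  expect_match(fmt$r2_adj, "^-?[0-9]+\\.[0-9]{4}$")
  expect_match(fmt$p_inverse, "^[0-9]+\\.[0-9]{2}$")
  expect_equal(fmt$size, "123,456")
})
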