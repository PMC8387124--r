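test_that("the bending hazard has the right value and limits", {
  expect_equal(bending_hazard(0.5, 100, 2), 200 * (1 - exp(-1)))
  # small-x limit mu1 * r_max
  expect_equal(bending_hazard(1e-9, 100, 3), 300, tolerance = 1e-6)
  # large-argument limit mu1 / x
  expect_equal(bending_hazard(1, 100, 50), 100, tolerance = 1e-12)
  # x = 0 returns the limit with a flag, not an error
  at0 <- bending_hazard(0, 100, 3)
  expect_equal(as.numeric(at0), 300)
  expect_true(attr(at0, "limit"))
  expect_error(bending_hazard(1, -1, 2))
})

test_that("the bending hazard is non-increasing in age", {
  set.seed(8)
  for (rep in 1:20) {
    mu1 <- exp(stats::runif(1, -8, 5))
    r_max <- exp(stats::runif(1, -3, 8))
    x <- sort(exp(stats::runif(50, -7, 3)))
    h <- bending_hazard(x, mu1, r_max)
    expect_true(all(diff(h) <= 1e-12 * h[-length(h)]))
  }
})

test_that("noise-free bending data are recovered to 1e-6 relative", {
  x <- midpoint(standard_age_grid(10))
  pts <- points_from_rates(x, bending_hazard(x, 120, 40))
  fit <- fit_bending(pts)
  expect_true(fit$converged)
  expect_equal(fit$mu1, 120, tolerance = 1e-6)
  expect_equal(fit$r_max, 40, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("on pure inverse data the bend runs out of the data", {
  x <- midpoint(standard_age_grid(10))
  pts <- points_from_rates(x, 0.08 / x)
  fit <- fit_bending(pts)
  # r_max escapes upward, the fitted curve approaches mu1 / x
  expect_gt(fit$r_max * min(x), 5)
  expect_lt(fit$rss, 1e-6)
  expect_equal(fit$mu1, 0.08, tolerance = 1e-3)
  # nesting: no finite r_max on a grid beats the attained fit
  rss_grid <- sapply(c(1, 5, 20, 100, 500), function(rm) {
    mu1_ls <- exp(mean(pts$lnmu - log(bending_hazard(pts$x, 1, rm))))
    sum((pts$lnmu - log(bending_hazard(pts$x, mu1_ls, rm)))^2)
  })
  expect_true(all(fit$rss <= rss_grid + 1e-12))
})

test_that("r_max is recovered within 15% median error from noisy counts", {
  rel_err <- sapply(1:60, function(i) {
    spec <- tiny_spec(profile_bending(0.06, 35), seed = 4000L + i,
                      countries = list(list(name = "Alpha", years = 2000:2002,
                                            pop_under1 = 5e5, pop_band = 5e5)))
    ds <- generate_dataset(spec)
    atm <- aggregate_atm(ds$deaths, ds$population, "Alpha", 2000:2002)
    fit <- fit_bending(atm, c(0, 10))
    abs(fit$r_max - 35) / 35
  })
  expect_lt(stats::median(rel_err), 0.15)
})

test_that("a homogeneous cohort shows a flat hazard at its risk", {
  r0 <- 0.02
  spec <- frailty_spec(2e5, "point_mass", r_point = r0, horizon = 15,
                       seed = 77L)
  sim <- simulate_frailty(spec, standard_age_grid(15))
  # death counts within 3 sigma of the binomial expectation per category
  surv <- exp(-r0 * sim$lower) - exp(-r0 * sim$upper)
  expect_true(all(abs(sim$deaths - 2e5 * surv) <= 3 * sqrt(2e5 * surv) + 1))
  # empirical hazard flat at r0
  se <- sqrt(pmax(sim$deaths, 1)) / sim$person_years
  expect_true(all(abs(sim$rate - r0) <= 3 * se))
})

test_that("simulation is deterministic under the seed", {
  spec <- frailty_spec(1e4, "reciprocal", r_min = 1e-6, r_max = 10,
                       horizon = 15, seed = 123L)
  s1 <- simulate_frailty(spec)
  s2 <- simulate_frailty(spec)
  expect_identical(s1$deaths, s2$deaths)
  expect_identical(s1$person_years, s2$person_years)
})

test_that("the simulator horizon must cover the grid", {
  spec <- frailty_spec(10, "point_mass", r_point = 1, horizon = 5, seed = 1L)
  expect_error(simulate_frailty(spec, standard_age_grid(15)), "horizon")
})

test_that("the quadrature oracle matches closed forms", {
  # point mass: hazard is the risk itself at every age
  pm <- frailty_spec(10, "point_mass", r_point = 3.5, horizon = 15, seed = 1L)
  expect_equal(mixture_hazard_oracle(pm, c(0.01, 1, 9)), rep(3.5, 3))

  # reciprocal density: closed form via the exponential integral,
  # h(x) = (exp(-rmin x) - exp(-rmax x)) / (x [E1(rmin x) - E1(rmax x)])
  sp <- frailty_spec(10, "reciprocal", r_min = 1e-6, r_max = 100,
                     horizon = 15, seed = 1L)
  for (x in c(0.01, 0.1, 1, 5)) {
    closed <- (exp(-sp$r_min * x) - exp(-sp$r_max * x)) /
      (x * (pracma::expint_E1(sp$r_min * x) - pracma::expint_E1(sp$r_max * x)))
    expect_equal(mixture_hazard_oracle(sp, x), closed, tolerance = 1e-7)
  }

  # before any depletion the mixture hazard is the mean risk
  low <- frailty_spec(10, "reciprocal", r_min = 1e-4, r_max = 1e-3,
                      horizon = 15, seed = 1L)
  mean_r <- (low$r_max - low$r_min) / log(low$r_max / low$r_min)
  expect_equal(mixture_hazard_oracle(low, 0.001), mean_r, tolerance = 1e-4)
})

test_that("the reciprocal mixture hazard scales as 1/x in the window", {
  sp <- frailty_spec(10, "reciprocal", r_min = 1e-18, r_max = 1e4,
                     horizon = 15, seed = 1L)
  x <- c(0.01, 0.05, 0.2, 1, 5)
  h <- mixture_hazard_oracle(sp, x)
  local_slope <- diff(log(h)) / diff(log(x))
  expect_true(all(local_slope > -1.05 & local_slope < -0.95))
})

test_that("empirical hazards agree with the brute-force mixture oracle", {
  spec <- frailty_spec(3e5, "reciprocal", r_min = 1e-6, r_max = 10,
                       horizon = 15, seed = 99L)
  grid <- standard_age_grid(15)
  sim <- simulate_frailty(spec, grid)

  # bin-level oracle: expected deaths and exposure from the mixture
  # survival S(x) = E[exp(-r x)], integrated by quadrature on log-r
  S <- function(x) {
    sapply(x, function(xx) {
      stats::integrate(function(s) exp(-xx * exp(s)), log(spec$r_min),
                       log(spec$r_max), rel.tol = 1e-10,
                       subdivisions = 2000L)$value /
        log(spec$r_max / spec$r_min)
    })
  }
  for (i in seq_len(nrow(grid))) {
    ED <- spec$n_individuals * (S(grid$lower[i]) - S(grid$upper[i]))
    EL <- spec$n_individuals *
      stats::integrate(function(u) S(u), grid$lower[i], grid$upper[i],
                       rel.tol = 1e-8)$value
    se <- sqrt(ED) / EL
    expect_lt(abs(sim$rate[i] - ED / EL), 3.5 * se)
  }

  # and the midpoint oracle tracks the bin rate to leading order
  h_mid <- mixture_hazard_oracle(spec, midpoint(grid))
  expect_true(all(abs(log(sim$rate / h_mid)) < 0.35))
})

test_that("user-table mixtures are validated and evaluated discretely", {
  tab <- data.frame(r = c(0.01, 1), weight = c(0.9, 0.1))
  sp <- frailty_spec(10, "user_table", r_min = 1e-3, r_max = 2, horizon = 15,
                     seed = 1L, table = tab)
  x <- 2
  w <- tab$weight * exp(-tab$r * x)
  expect_equal(mixture_hazard_oracle(sp, x), sum(w * tab$r) / sum(w))
  expect_error(frailty_spec(10, "user_table", horizon = 15, seed = 1L,
                            table = data.frame(r = 1, weight = -1)),
               "positive")
})
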