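#' Synthetic WHO-layout data generator
#'
#' Emits multi-country, multi-year death-count and population tables in
#' the same tidy layout as the loaders in this package, from known hazard
#' profiles with Poisson count noise. Expected deaths for a country-year,
#' cause and age category are `lambda = profile(midpoint) * L` with L the
#' stationary exposure of the category (under-1 count times band width for
#' infant subcategories, the band count otherwise). Counts are Poisson
#' because rates are far below one per person-year everywhere except the
#' first day of life; a binomial draw can be requested for that band.
#' A truth record carrying every lambda and profile parameter is always
#' emitted beside the data so that oracle tests never have to reconstruct
#' it.
#'
#' A TOTAL cause is never drawn independently: it is defined as the sum of
#' the generated components, so conservation over cause groups holds by
#' construction.
#'
#' @name synthetic
NULL

#' Hazard profiles for the generator
#'
#' * `profile_inverse(c)` — mu(x) = c / x, the inverse proportion.
#' * `profile_bending(mu1, r_max)` — the bending hazard of
#'   [bending_hazard()].
#' * `profile_constant(m)` — age-independent rate m.
#' * `profile_neoplasm(c_infant, m_const)` — inverse decline c/x during
#'   the first year, then the age-independent rate m (the shape reported
#'   for neoplasm mortality).
#'
#' @param c,mu1,r_max,m,c_infant,m_const Positive parameters; rates per
#'   person-year at the stated ages.
#' @return An object of class `"hazard_profile"` with elements `type`,
#'   `params` and the vectorised function `fn(x)`.
#' @rdname hazard-profiles
#' @export
profile_inverse <- function(c) {
  stopifnot(c > 0)
  structure(list(type = "inverse", params = list(c = c),
                 fn = function(x) c / x), class = "hazard_profile")
}

#' @rdname hazard-profiles
#' @export
profile_bending <- function(mu1, r_max) {
  stopifnot(mu1 > 0, r_max > 0)
  structure(list(type = "bending", params = list(mu1 = mu1, r_max = r_max),
                 fn = function(x) bending_hazard(x, mu1, r_max)),
            class = "hazard_profile")
}

#' @rdname hazard-profiles
#' @export
profile_constant <- function(m) {
  stopifnot(m >= 0)
  structure(list(type = "constant", params = list(m = m),
                 fn = function(x) rep(m, length(x))), class = "hazard_profile")
}

#' @rdname hazard-profiles
#' @export
profile_neoplasm <- function(c_infant, m_const) {
  stopifnot(c_infant > 0, m_const > 0)
  structure(list(type = "neoplasm",
                 params = list(c_infant = c_infant, m_const = m_const),
                 fn = function(x) ifelse(x < 1, c_infant / x, m_const)),
            class = "hazard_profile")
}

#' Specify a synthetic dataset
#'
#' @param countries List of country entries, each a list with `name`,
#'   `years` (vector of calendar years), `pop_under1` (mean population
#'   below age 1) and `pop_band` (mean population of each whole-year band:
#'   a single number applied to all bands, or a named vector by band
#'   label).
#' @param profiles Named list of `hazard_profile` objects, one per cause;
#'   the names become the `cause` column of the death table.
#' @param grid An `age_grid`.
#' @param seed Mandatory integer seed.
#' @param binomial_first_day If `TRUE`, draw the "0 days" counts as
#'   binomial with the matching expectation instead of Poisson.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(countries, profiles, grid = standard_age_grid(),
                           seed, binomial_first_day = FALSE) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(length(countries) >= 1, length(profiles) >= 1)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop("profiles must be a named list (names are cause labels)", call. = FALSE)
  }
  if ("TOTAL" %in% names(profiles)) {
    stop("TOTAL is defined as the sum of components and cannot be drawn",
         call. = FALSE)
  }
  for (p in profiles) stopifnot(inherits(p, "hazard_profile"))
  for (ct in countries) {
    stopifnot(!is.null(ct$name), length(ct$years) >= 1,
              ct$pop_under1 > 0, all(ct$pop_band > 0))
  }
  structure(list(countries = countries, profiles = profiles, grid = grid,
                 seed = as.integer(seed),
                 binomial_first_day = isTRUE(binomial_first_day)),
            class = "synthetic_spec")
}

country_exposures <- function(ct, grid) {
  vapply(seq_len(nrow(grid)), function(i) {
    if (grid$band[i] == "infant_sub") {
      ct$pop_under1 * (grid$upper[i] - grid$lower[i])
    } else if (length(ct$pop_band) == 1L && is.null(names(ct$pop_band))) {
      ct$pop_band
    } else {
      v <- ct$pop_band[[grid$label[i]]]
      if (is.null(v)) stop("no population for band '", grid$label[i],
                           "' in country ", ct$name, call. = FALSE)
      v
    }
  }, numeric(1))
}

#' Generate a synthetic dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `deaths` (a `death_counts` table),
#'   `population` (a `population_counts` table) and `truth` (a data frame
#'   of every record's expected count `lambda` plus, as attribute
#'   `profiles`, the generating parameters). Identical specs produce
#'   identical output.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  grid <- spec$grid
  mids <- midpoint(grid)
  drec <- list(); prec <- list(); k <- 0L
  for (ct in spec$countries) {
    expo <- country_exposures(ct, grid)
    for (yr in ct$years) {
      prec[[length(prec) + 1L]] <- data.frame(
        country = ct$name, year = yr,
        age_band = c("under-1", grid$label[grid$band == "whole_year"]),
        count = c(ct$pop_under1, expo[grid$band == "whole_year"]),
        stringsAsFactors = FALSE)
      for (cause in names(spec$profiles)) {
        lam <- spec$profiles[[cause]]$fn(mids) * expo
        if (any(!is.finite(lam))) {
          stop("hazard profile '", cause, "' undefined at a grid midpoint",
               call. = FALSE)
        }
        deaths <- stats::rpois(length(lam), lam)
        if (spec$binomial_first_day) {
          i1 <- which(grid$label == "0 days")
          pr <- lam[i1] / ct$pop_under1
          deaths[i1] <- stats::rbinom(1L, round(ct$pop_under1), min(pr, 1))
        }
        k <- k + 1L
        drec[[k]] <- data.frame(country = ct$name, year = yr, cause = cause,
                                age_label = grid$label, deaths = deaths,
                                lambda = lam, stringsAsFactors = FALSE)
      }
    }
  }
  all_d <- do.call(rbind, drec)
  truth <- all_d[, c("country", "year", "cause", "age_label", "lambda")]
  attr(truth, "profiles") <- lapply(spec$profiles, function(p)
    c(list(type = p$type), p$params))
  deaths <- as_death_counts(all_d[, c("country", "year", "cause",
                                      "age_label", "deaths")])
  pop <- do.call(rbind, prec)
  class(pop) <- c("population_counts", "data.frame")
  list(deaths = deaths, population = pop, truth = truth)
}

#' Write a generated dataset to disk
#'
#' Emits `deaths.csv` and `population.csv` in the loader dialects plus
#' `truth.json` with every expected count and the generating parameters.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
emit_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(spec)
  write_death_counts(ds$deaths, file.path(dir, "deaths.csv"))
  write_population(ds$population, file.path(dir, "population.csv"))
  jsonlite::write_json(
    list(records = ds$truth, profiles = attr(ds$truth, "profiles"),
         seed = spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build a synthetic spec from a configuration list
#'
#' Convenience constructor for configuration files: `config` carries
#' `countries` (each with `name`, `years` as c(first, last) or a vector,
#' `pop_under1`, `pop_band`), `profiles` (name -> list with `type` and
#' the profile's parameters), `seed` and optionally `grid_upper`.
#'
#' @param config List, e.g. from [yaml::read_yaml()].
#' @return A [synthetic_spec()].
#' @export
synthetic_spec_from_config <- function(config) {
  countries <- lapply(config$countries, function(ct) {
    yrs <- unlist(ct$years)
    if (length(yrs) == 2L && yrs[2] > yrs[1] + 1) yrs <- seq(yrs[1], yrs[2])
    list(name = ct$name, years = yrs, pop_under1 = ct$pop_under1,
         pop_band = unlist(ct$pop_band))
  })
  profiles <- lapply(config$profiles, function(p) {
    switch(p$type,
           inverse = profile_inverse(p$c),
           bending = profile_bending(p$mu1, p$r_max),
           constant = profile_constant(p$m),
           neoplasm = profile_neoplasm(p$c_infant, p$m_const),
           stop("unknown profile type: ", p$type, call. = FALSE))
  })
  names(profiles) <- names(config$profiles)
  grid <- standard_age_grid(if (is.null(config$grid_upper)) 15
                            else config$grid_upper)
  synthetic_spec(countries, profiles, grid = grid, seed = config$seed)
}

#' Repeated-generation recovery experiment
#'
#' Runs generate -> aggregate -> fit -> nested inverse test over many
#' replicates of one spec (replicate seeds derived from `seed`), and
#' summarises how well the inferential machinery recovers the generating
#' truth: bias and RMSE of the slope estimate, coverage of its confidence
#' interval, and the fraction of replicates in which the inverse
#' proportion is rejected at alpha = 0.05.
#'
#' The spec must use a single hazard profile. For an inverse profile the
#' truth is gamma = -1 and mu1 = c; for other profiles pass `true_gamma`
#' explicitly (coverage and bias are skipped when no truth applies).
#'
#' @param spec A [synthetic_spec()] with exactly one profile.
#' @param n_replicates Number of replicates.
#' @param seed Master seed for the experiment.
#' @param age_range Fitting range, default `c(0, 10)`.
#' @param ci_level Confidence level, default 0.95.
#' @param true_gamma True slope; defaults to -1 for an inverse profile.
#' @return List with the per-replicate `estimates` data frame and
#'   summaries `gamma_mean`, `gamma_bias`, `gamma_rmse`,
#'   `coverage_gamma`, `reject_rate`, `n_used`.
#' @export
recovery_experiment <- function(spec, n_replicates, seed,
                                age_range = c(0, 10), ci_level = 0.95,
                                true_gamma = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1)
  if (length(spec$profiles) != 1L) {
    stop("recovery experiment requires a single-profile spec", call. = FALSE)
  }
  prof <- spec$profiles[[1]]
  if (is.null(true_gamma) && prof$type == "inverse") true_gamma <- -1
  countries <- vapply(spec$countries, `[[`, "", "name")
  years <- lapply(spec$countries, `[[`, "years")
  names(years) <- countries
  grid <- spec$grid

  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    sp <- spec
    sp$seed <- (seed + i) %% .Machine$integer.max
    ds <- generate_dataset(sp)
    atm <- aggregate_atm(ds$deaths, ds$population, countries, years,
                         group = cg_total(), grid = grid,
                         population_name = "synthetic")
    res <- tryCatch({
      pts <- loglog_points(atm, age_range)
      fit <- fit_loglog(pts, ci_level = ci_level)
      inv <- test_inverse(pts, fit)
      data.frame(gamma = fit$gamma, lower = fit$ci_lower,
                 upper = fit$ci_upper, ln_mu1 = fit$ln_mu1,
                 p_inverse = inv$p_value, ok = TRUE)
    }, error = function(e) data.frame(gamma = NA_real_, lower = NA_real_,
                                      upper = NA_real_, ln_mu1 = NA_real_,
                                      p_inverse = NA_real_, ok = FALSE))
    rows[[i]] <- res
  }
  est <- do.call(rbind, rows)
  ok <- est$ok
  out <- list(estimates = est, n_used = sum(ok),
              reject_rate = mean(est$p_inverse[ok] < 0.05))
  if (!is.null(true_gamma)) {
    out$gamma_mean <- mean(est$gamma[ok])
    out$gamma_bias <- mean(est$gamma[ok]) - true_gamma
    out$gamma_rmse <- sqrt(mean((est$gamma[ok] - true_gamma)^2))
    out$coverage_gamma <- mean(est$lower[ok] <= true_gamma &
                                 est$upper[ok] >= true_gamma)
  }
  out
}
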