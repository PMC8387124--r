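#' Halley aggregation of deaths and exposures
#'
#' Deaths and population counts from several countries and calendar years
#' are pooled into one hypothetical population before any rate is computed:
#' per age category, the pooled death count D_i is the plain sum of deaths
#' over the selected country-years, the pooled exposure L_i is the sum of
#' person-years, and the age-specific mortality rate is mu_i = D_i / L_i
#' per person-year. Pooling exists to remove zero-death categories that
#' would otherwise make a log-scale trajectory unconstructible.
#'
#' Exposure follows the stationary-population reading of census counts: a
#' mid-year mean population count contributes one person-year per person
#' for a whole-year band, and an infant subcategory receives the under-1
#' count multiplied by the width of the subcategory in years.
#'
#' @name halley
NULL

# Normalizes a country/year selection into explicit (country, year) pairs.
# `years` is either a vector applied to every country or a named list of
# per-country year vectors; mismatched calendar coverage must be stated
# explicitly, never intersected silently.
selection_pairs <- function(countries, years) {
  if (length(countries) == 0L) stop("empty country selection", call. = FALSE)
  if (is.list(years)) {
    miss <- setdiff(countries, names(years))
    if (length(miss)) {
      stop("no year list given for countries: ", paste(miss, collapse = ", "),
           "; per-country year lists are required when coverage differs",
           call. = FALSE)
    }
    do.call(rbind, lapply(countries, function(ct) {
      if (length(years[[ct]]) == 0L) stop("empty year list for ", ct, call. = FALSE)
      data.frame(country = ct, year = years[[ct]], stringsAsFactors = FALSE)
    }))
  } else {
    if (length(years) == 0L) stop("empty year selection", call. = FALSE)
    expand.grid(country = countries, year = years,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
}

#' Person-years of exposure for one age category
#'
#' @param pop A `population_counts` table.
#' @param category One row of an `age_grid`.
#' @param countries Character vector of countries to pool.
#' @param years Either a numeric vector of calendar years applied to every
#'   country, or a named list mapping each country to its own year vector.
#' @return Total person-years, a positive scalar.
#' @examples
#' pop <- data.frame(country = "A", year = 2000,
#'                   age_band = c("under-1", "5-9 years"),
#'                   count = c(365000, 50000))
#' g <- standard_age_grid(10)
#' person_years(pop, g[g$label == "0 days", ], "A", 2000)     # 1000
#' person_years(pop, g[g$label == "5-9 years", ], "A", 2000)  # 50000
#' @export
person_years <- function(pop, category, countries, years) {
  sel <- selection_pairs(countries, years)
  band <- if (category$band == "infant_sub") "under-1" else category$label
  width <- if (category$band == "infant_sub") category$upper - category$lower else 1
  total <- 0
  for (i in seq_len(nrow(sel))) {
    hit <- pop$country == sel$country[i] & pop$year == sel$year[i] &
      pop$age_band == band
    if (!any(hit)) {
      stop("no population record for (", sel$country[i], ", ", sel$year[i],
           ") band '", band, "'", call. = FALSE)
    }
    total <- total + sum(pop$count[hit]) * width
  }
  if (total <= 0) stop("non-positive person-years for '", category$label, "'",
                       call. = FALSE)
  total
}

#' Aggregate an age trajectory of mortality
#'
#' Pools deaths and exposures over a country/year selection and a cause
#' group and returns the age-specific rates. Categories with zero pooled
#' deaths are retained but flagged unusable: log-scale fitting refuses
#' them, and the caller decides whether to widen the pooling.
#'
#' @param deaths A `death_counts` table.
#' @param pop A `population_counts` table.
#' @param countries,years Selection as in [person_years()].
#' @param group A `cause_group`; default [cg_total()].
#' @param grid An `age_grid`.
#' @param population_name Label for the pooled population; defaults to the
#'   countries pasted together.
#' @return An object of class `"atm"`: a data frame with one row per age
#'   category (`label`, `lower`, `upper`, `band`, `x` midpoint in years,
#'   `deaths`, `person_years`, `rate` per person-year, `usable`) plus
#'   attributes `population` and `cause_group`.
#' @export
aggregate_atm <- function(deaths, pop, countries, years, group = cg_total(),
                          grid = standard_age_grid(10),
                          population_name = paste(countries, collapse = "+")) {
  sel <- selection_pairs(countries, years)
  d <- resolve_cause_group(group, deaths)
  in_sel <- paste(d$country, d$year) %in% paste(sel$country, sel$year)
  d <- d[in_sel, , drop = FALSE]

  D <- vapply(grid$label, function(lab) {
    as.double(sum(d$deaths[d$age_label == lab]))
  }, numeric(1))
  L <- vapply(seq_len(nrow(grid)), function(i) {
    person_years(pop, grid[i, , drop = FALSE], countries, years)
  }, numeric(1))

  out <- data.frame(label = grid$label, lower = grid$lower, upper = grid$upper,
                    band = grid$band, x = midpoint(grid), deaths = D,
                    person_years = L, rate = D / L, usable = D > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("atm", "data.frame"),
            population = population_name, cause_group = group$name)
}

#' Pool already-aggregated trajectories
#'
#' Halley pooling is associative: summing the deaths and person-years of
#' two disjoint aggregations equals aggregating their union directly.
#'
#' @param ... `atm` objects on identical grids and cause group.
#' @param population_name Name for the pooled result.
#' @return An `atm`.
#' @export
pool_atm <- function(..., population_name = "pooled") {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  base <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(p$label, base$label)) {
      stop("trajectories are on different age grids", call. = FALSE)
    }
    if (!identical(attr(p, "cause_group"), attr(base, "cause_group"))) {
      stop("trajectories have different cause groups", call. = FALSE)
    }
    base$deaths <- base$deaths + p$deaths
    base$person_years <- base$person_years + p$person_years
  }
  base$rate <- base$deaths / base$person_years
  base$usable <- base$deaths > 0
  attr(base, "population") <- population_name
  base
}

#' Share of deaths attributable to a cause group
#'
#' The ratio of pooled deaths in `atm_group` to pooled deaths in
#' `atm_total`, over the age categories whose midpoints lie inside
#' `age_range`.
#'
#' @param atm_group,atm_total `atm` objects aggregated on the same
#'   population and grid; `atm_total` is the all-cause trajectory.
#' @param age_range Length-2 numeric `(lower, upper)` in years.
#' @return A fraction in `[0, 1]`.
#' @export
death_share <- function(atm_group, atm_total, age_range) {
  if (!identical(atm_group$label, atm_total$label)) {
    stop("trajectories are on different age grids", call. = FALSE)
  }
  m <- atm_total$x > age_range[1] & atm_total$x < age_range[2]
  tot <- sum(atm_total$deaths[m])
  if (tot == 0) stop("zero total deaths in the age range: share undefined",
                     call. = FALSE)
  sum(atm_group$deaths[m]) / tot
}

#' @export
print.atm <- function(x, ...) {
  cat("Age trajectory of mortality -", attr(x, "population"),
      "/", attr(x, "cause_group"), "\n")
  df <- as.data.frame(x)
  df$rate_per_1000py <- 1000 * df$rate
  print.data.frame(df[, c("label", "x", "deaths", "person_years",
                          "rate_per_1000py", "usable")], digits = 4, ...)
  invisible(x)
}

#' Write an aggregated trajectory to CSV
#'
#' Columns: `population, cause_group, age_label, x_years, deaths,
#' person_years, rate_per_1000py`. Rates are reported per 1000
#' person-years; the internal unit is per person-year.
#'
#' @param atm An `atm` object.
#' @param path Output CSV path.
#' @param scale Reporting scale for the rate column (person-years per
#'   reporting unit), default 1000.
#' @export
write_atm <- function(atm, path, scale = 1000) {
  df <- data.frame(population = attr(atm, "population"),
                   cause_group = attr(atm, "cause_group"),
                   age_label = atm$label, x_years = atm$x,
                   deaths = atm$deaths, person_years = atm$person_years,
                   rate_per_1000py = scale * atm$rate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
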