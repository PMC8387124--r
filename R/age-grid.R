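#' Age categories and age grids
#'
#' An age grid is the demographic partition of childhood ages used throughout
#' the package: the four sub-year infant categories of the WHO mortality
#' database ("0 days", "1-6 days", "7-27 days", "28-365 days") followed by
#' multi-year bands (1-4 years, 5-9 years, ...). Category bounds are
#' half-open intervals `[lower, upper)` in years; day-denominated bounds are
#' converted at 365 days per year so that the four infant categories tile the
#' first year of life exactly.
#'
#' @name age-grid
NULL

DAYS_PER_YEAR <- 365

#' Construct a single age category
#'
#' @param label Text label as it appears in input tables.
#' @param lower,upper Bounds in years, half-open `[lower, upper)`.
#' @param band Either `"infant_sub"` (a subdivision of the first year of
#'   life) or `"whole_year"`.
#' @return A one-row data frame with columns `label`, `lower`, `upper`,
#'   `band` and `midpoint`.
#' @examples
#' age_category("5-9 years", 5, 10, "whole_year")
#' @export
age_category <- function(label, lower, upper, band = c("whole_year", "infant_sub")) {
  band <- match.arg(band)
  stopifnot(is.character(label), length(label) == 1L)
  if (!(is.numeric(lower) && is.numeric(upper) && lower >= 0 && lower < upper)) {
    stop("age category bounds must satisfy 0 <= lower < upper, got [",
         lower, ", ", upper, ")", call. = FALSE)
  }
  data.frame(label = label, lower = lower, upper = upper, band = band,
             midpoint = (lower + upper) / 2, stringsAsFactors = FALSE)
}

#' Assemble an age grid from categories
#'
#' Categories must be contiguous (each upper bound equals the next lower
#' bound), start at age 0, and any infant subcategories must tile the first
#' year exactly.
#'
#' @param ... One-row data frames from [age_category()], in any order.
#' @return A data frame of class `"age_grid"`, sorted by lower bound.
#' @export
age_grid <- function(...) {
  g <- do.call(rbind, list(...))
  g <- g[order(g$lower), , drop = FALSE]
  rownames(g) <- NULL
  if (g$lower[1] != 0) stop("age grid must start at age 0", call. = FALSE)
  if (nrow(g) > 1 && any(abs(g$upper[-nrow(g)] - g$lower[-1]) > 1e-12)) {
    stop("age grid has gaps or overlaps between adjacent categories", call. = FALSE)
  }
  inf <- g$band == "infant_sub"
  if (any(inf)) {
    w <- sum(g$upper[inf] - g$lower[inf])
    if (abs(w - 1) > 1e-9) {
      stop("infant subcategories must tile (0, 1) year exactly; widths sum to ",
           format(w), call. = FALSE)
    }
  }
  if (anyDuplicated(g$label)) stop("duplicate age category labels", call. = FALSE)
  class(g) <- c("age_grid", "data.frame")
  g
}

#' The standard WHO-style age grid
#'
#' Four infant subcategories — (0, 1) day, (1, 7) days, (7, 28) days,
#' (28, 365) days — then whole-year bands (1, 5), (5, 10), ... up to
#' `upper_limit` years.
#'
#' @param upper_limit Upper age bound in years; must be one of the standard
#'   band boundaries (5, 10, 15, 20, ...).
#' @return An `age_grid`.
#' @examples
#' standard_age_grid(10)
#' @export
standard_age_grid <- function(upper_limit = 15) {
  d <- DAYS_PER_YEAR
  cats <- list(
    age_category("0 days",      0,       1 / d,   "infant_sub"),
    age_category("1-6 days",    1 / d,   7 / d,   "infant_sub"),
    age_category("7-27 days",   7 / d,  28 / d,   "infant_sub"),
    age_category("28-365 days", 28 / d,  1,       "infant_sub")
  )
  bounds <- c(1, seq(5, upper_limit, by = 5))
  if (upper_limit < 5 || upper_limit %% 5 != 0) {
    stop("upper_limit must be a multiple of 5 years, >= 5", call. = FALSE)
  }
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    cats[[length(cats) + 1L]] <-
      age_category(sprintf("%d-%d years", lo, hi - 1), lo, hi, "whole_year")
  }
  do.call(age_grid, cats)
}

#' Representative age of a category
#'
#' The arithmetic mean of the interval endpoints, in years. Day-denominated
#' categories are converted at 365 days per year, so "1-6 days" — the
#' interval (1, 7) days — has midpoint 4/365 years.
#'
#' @param category One or more rows of an `age_grid`.
#' @return Numeric vector of midpoints in years.
#' @export
midpoint <- function(category) {
  (category$lower + category$upper) / 2
}

#' Look up the grid categories whose midpoints fall in an age range
#'
#' @param grid An `age_grid`.
#' @param age_range Length-2 numeric `(lower, upper)` in years.
#' @return The matching rows of `grid`.
#' @keywords internal
grid_in_range <- function(grid, age_range) {
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2])
  m <- midpoint(grid)
  grid[m > age_range[1] & m < age_range[2], , drop = FALSE]
}

#' @export
print.age_grid <- function(x, ...) {
  cat("Age grid:", nrow(x), "categories covering [0,", max(x$upper), ") years\n")
  print.data.frame(x, ...)
  invisible(x)
}
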