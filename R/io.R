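#' Readers and writers for the tabular inputs
#'
#' Death counts and population counts travel as tidy UTF-8 CSV files with
#' "." as the decimal separator:
#'
#' * deaths: `country,year,cause,age_label,deaths`
#' * population: `country,year,age_band,count` where `age_band` is either a
#'   whole-year grid label ("1-4 years", ...) or `"under-1"` for the mean
#'   population below age one.
#'
#' The raw fixed-column WHO dump is out of scope; [who_converter_stub()]
#' documents the mapping a converter would have to perform.
#'
#' @name io
NULL

# Labels that mean "first year of life, not subdivided". A country-year using
# one of these fails the eligibility rule that infant deaths be split into
# the four subcategories.
COARSE_INFANT_LABELS <- c("0-365 days", "under-1", "under 1", "0 years",
                          "<1 year", "0")

#' Load a death-count table
#'
#' Validates the WHO-layout tidy CSV against an age grid. Age labels must
#' either match a grid category or be a single-year integer label (e.g.
#' `"2 years"`), which is summed into the whole-year category containing
#' it. Country-years whose infant deaths are not split into the four
#' sub-year categories are rejected: the eligibility criterion for
#' inclusion in a pooled analysis.
#'
#' @param path CSV file with header `country,year,cause,age_label,deaths`.
#' @param grid An `age_grid` giving the admissible categories.
#' @return A data frame of class `"death_counts"` with one record per
#'   (country, year, cause, age_label).
#' @export
load_death_counts <- function(path, grid = standard_age_grid()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "year", "cause", "age_label", "deaths")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("death-count file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) == 0L) {
    warning("empty death-count file: ", path, call. = FALSE)
    return(as_death_counts(d[, need]))
  }
  if (any(d$deaths < 0)) stop("negative death counts found", call. = FALSE)
  if (any(d$deaths != round(d$deaths))) {
    stop("death counts must be integers", call. = FALSE)
  }

  coarse <- d$age_label %in% COARSE_INFANT_LABELS
  if (any(coarse)) {
    cy <- unique(paste(d$country[coarse], d$year[coarse]))
    stop("infant deaths not split into the four sub-year age categories for ",
         "country-year(s): ", paste(cy, collapse = "; "),
         " (labels such as '0-365 days' are not eligible)", call. = FALSE)
  }

  d$age_label <- map_age_labels(d$age_label, grid)
  # single-year labels mapped onto one band may now collide: sum them
  d <- stats::aggregate(deaths ~ country + year + cause + age_label, data = d,
                        FUN = sum)
  as_death_counts(d[, need])
}

# Maps single-year labels ("1", "3 years") into the containing whole-year
# category; leaves grid labels untouched; errors on anything else.
map_age_labels <- function(labels, grid) {
  known <- labels %in% grid$label
  out <- labels
  unk <- unique(labels[!known])
  for (lab in unk) {
    yr <- suppressWarnings(as.numeric(sub("[[:space:]]*years?$", "", lab)))
    row <- if (!is.na(yr) && yr >= 1) which(grid$lower <= yr & grid$upper > yr)
           else integer(0)
    if (length(row) != 1L) {
      stop("unknown age label(s): ", paste(unk, collapse = ", "), call. = FALSE)
    }
    out[labels == lab] <- grid$label[row]
  }
  out
}

as_death_counts <- function(d) {
  key <- paste(d$country, d$year, d$cause, d$age_label, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (country, year, cause, age_label) records", call. = FALSE)
  }
  d <- d[order(d$country, d$year, d$cause, d$age_label), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("death_counts", "data.frame")
  d
}

#' Load a population table
#'
#' @param path CSV file with header `country,year,age_band,count`. Counts
#'   are mid-year mean populations; one count equals one person-year of
#'   exposure for its band.
#' @return A data frame of class `"population_counts"`.
#' @export
load_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "year", "age_band", "count")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("population file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(p$count <= 0)) stop("population counts must be > 0", call. = FALSE)
  p <- p[order(p$country, p$year, p$age_band), need, drop = FALSE]
  rownames(p) <- NULL
  class(p) <- c("population_counts", "data.frame")
  p
}

#' Write death-count and population tables
#'
#' Inverse of the loaders; a written table reloads record-for-record.
#'
#' @param x The table.
#' @param path Output CSV path.
#' @rdname io-write
#' @export
write_death_counts <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io-write
#' @export
write_population <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Converter stub for the raw WHO fixed-column dump
#'
#' Parsing the historical fixed-column WHO mortality files (with their
#' per-country age-format codes) is out of scope. This stub documents the
#' target layout so that an external converter can be written: one row per
#' (country, year, cause, age_label) with integer deaths, age labels drawn
#' from [standard_age_grid()], and the four infant subcategories present
#' for every eligible country-year.
#'
#' @return Called for its message; returns `NULL` invisibly.
#' @export
who_converter_stub <- function() {
  message("Convert raw WHO mortality dumps to CSV with columns ",
          "country,year,cause,age_label,deaths; see ?load_death_counts.")
  invisible(NULL)
}
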