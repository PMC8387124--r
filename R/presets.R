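#' Named population presets
#'
#' Pooled-population analyses of the WHO mortality database conventionally
#' name their aggregates: P1 (five large western European countries), P2
#' (five central European countries), P3 (four Nordic countries), P14 (the
#' union of P1-P3), P4 (six South American countries), P5 (five further
#' non-European countries) and P25 (all twenty-five). The package bundles
#' the per-country mean population sizes and ICD-10 calendar periods of
#' this 25-country panel so that the pooling bookkeeping can be exercised
#' without any external download.
#'
#' @name presets
NULL

#' Catalogue of the 25-country panel
#'
#' @return Data frame with columns `country`, `period` (text,
#'   "first-last" calendar years of ICD-10 coverage with four infant age
#'   categories) and `size` (mean number of living persons per calendar
#'   year over that period).
#' @export
country_catalog <- function() {
  path <- system.file("extdata", "pooled-country-sizes.csv",
                      package = "atmort", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @return For `population_presets()`: named list mapping preset name to
#'   its member countries.
#' @rdname presets
#' @export
population_presets <- function() {
  p1 <- c("France", "Germany", "Italy", "Spain", "UK")
  p2 <- c("Czech Republic", "Austria", "Hungary", "Poland", "Slovakia")
  p3 <- c("Sweden", "Norway", "Denmark", "Finland")
  p4 <- c("Argentina", "Brazil", "Peru", "Venezuela", "Chile", "Colombia")
  p5 <- c("Mexico", "Japan", "Australia", "New Zealand", "USA")
  list(P1 = p1, P2 = p2, P3 = p3, P14 = c(p1, p2, p3), P4 = p4, P5 = p5,
       P25 = c(p1, p2, p3, p4, p5))
}

#' Pooled size of a named preset
#'
#' Sums the catalogued per-country mean population sizes over the preset's
#' members — the additive bookkeeping that underlies Halley pooling.
#'
#' @param preset Preset name, e.g. `"P25"`.
#' @param catalog Country catalogue, default [country_catalog()].
#' @return Total mean number of living persons per calendar year.
#' @examples
#' pooled_population_size("P1")
#' @export
pooled_population_size <- function(preset, catalog = country_catalog()) {
  members <- population_presets()[[preset]]
  if (is.null(members)) stop("undefined population preset: ", preset,
                             call. = FALSE)
  miss <- setdiff(members, catalog$country)
  if (length(miss)) stop("countries missing from the catalogue: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sum(as.numeric(catalog$size[match(members, catalog$country)]))
}

#' Per-country year vectors of a preset
#'
#' Expands the catalogued periods into explicit per-country year lists, as
#' required by [aggregate_atm()] when calendar coverage differs between
#' countries.
#'
#' @inheritParams pooled_population_size
#' @return Named list mapping each member country to its year vector.
#' @export
preset_years <- function(preset, catalog = country_catalog()) {
  members <- population_presets()[[preset]]
  if (is.null(members)) stop("undefined population preset: ", preset,
                             call. = FALSE)
  out <- lapply(members, function(ct) {
    per <- catalog$period[catalog$country == ct]
    if (length(per) != 1L) stop("no catalogue period for ", ct, call. = FALSE)
    bounds <- as.integer(strsplit(per, "-", fixed = TRUE)[[1]])
    seq(bounds[1], bounds[2])
  })
  names(out) <- members
  out
}
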