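#' End-to-end pipeline runs
#'
#' [run_atm()] chains the full analysis — load, aggregate, fit, test,
#' report — from a single configuration (an R list or a YAML file).
#' Progress and decisions (excluded zero-death categories, test outcomes at
#' alpha = 0.05) are logged via [message()] so they land on standard
#' error; results go only to files and the returned object, keeping
#' outputs pipeable. A thin command-line wrapper over these functions
#' ships in `inst/cli/atm.R`.
#'
#' @name pipeline
NULL

#' Resolve a predefined cause group by name
#'
#' @param name `"TOTAL"`, `"NEOPLASMS"`, `"OTHER_DISEASES"`, `"CACNS"` or
#'   `"CHAPTER_<roman>"`.
#' @return A `cause_group`.
#' @export
get_cause_group <- function(name) {
  if (grepl("^CHAPTER_", name)) return(cg_chapter(sub("^CHAPTER_", "", name)))
  switch(name,
         TOTAL = cg_total(),
         NEOPLASMS = cg_neoplasms(),
         OTHER_DISEASES = cg_other_diseases(),
         CACNS = cg_cacns(),
         stop("unknown cause group: ", name, call. = FALSE))
}

#' Read a run configuration
#'
#' @param path YAML file. Recognised fields: `deaths`, `population` (input
#'   CSV paths); `countries` + `years` (vector or per-country mapping) or
#'   `preset`; `cause_group` (name, default TOTAL); `age_range` (two
#'   numbers, default 0 10); `ci_level` (default 0.95); `scale` (default
#'   1000); `grid_upper` (default 15); `out_dir`; `population_name`.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  defaults <- list(cause_group = "TOTAL", age_range = c(0, 10),
                   ci_level = 0.95, scale = 1000, grid_upper = 15,
                   out_dir = NULL, population_name = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (!is.null(config$preset)) {
    presets <- population_presets()
    if (is.null(presets[[config$preset]])) {
      stop("undefined population preset: ", config$preset, call. = FALSE)
    }
    config$countries <- presets[[config$preset]]
    if (is.null(config$years)) config$years <- preset_years(config$preset)
    if (is.null(config$population_name)) config$population_name <- config$preset
  }
  if (is.null(config$deaths) || is.null(config$population)) {
    stop("config must name 'deaths' and 'population' input files", call. = FALSE)
  }
  if (is.null(config$countries) || is.null(config$years)) {
    stop("config must select countries and years (or a preset)", call. = FALSE)
  }
  if (is.null(config$population_name)) {
    config$population_name <- paste(config$countries, collapse = "+")
  }
  config$age_range <- as.numeric(unlist(config$age_range))
  config
}

#' Run the aggregate-fit-report chain
#'
#' @param config Configuration list or path to a YAML file; see
#'   [read_run_config()].
#' @return Invisibly, a list with the aggregated `atm`, the `loglog_fit`,
#'   the `inverse_test`, the curvature and residual-independence results,
#'   the mortality-minimum row and the one-row `report`. When `out_dir` is
#'   set, `atm.csv`, `report.csv` and `report.json` are written there.
#' @export
run_atm <- function(config) {
  cfg <- normalize_config(config)
  grid <- standard_age_grid(cfg$grid_upper)
  group <- get_cause_group(cfg$cause_group)

  message("loading death counts from ", cfg$deaths)
  deaths <- load_death_counts(cfg$deaths, grid)
  message("loading population counts from ", cfg$population)
  pop <- load_population(cfg$population)

  atm <- aggregate_atm(deaths, pop, cfg$countries, cfg$years, group = group,
                       grid = grid, population_name = cfg$population_name)
  nzero <- sum(!atm$usable)
  if (nzero > 0) {
    message(nzero, " zero-death categories flagged unusable: ",
            paste(atm$label[!atm$usable], collapse = ", "))
  }

  pts <- loglog_points(atm, cfg$age_range)
  curv <- if (nrow(pts) >= 4) test_curvature(pts) else NULL
  if (!is.null(curv)) {
    message(sprintf("curvature test: p = %.4g (%s at alpha = 0.05)",
                    curv$p_quad,
                    if (curv$rejected) "curved" else "linear retained"))
  }
  fit <- fit_loglog(pts, ci_level = cfg$ci_level, scale = cfg$scale)
  inv <- test_inverse(pts, fit)
  message(sprintf("slope gamma = %.4f; inverse-proportion test p = %.4g (%s)",
                  fit$gamma, inv$p_value,
                  if (inv$rejected) "rejected" else "not rejected"))
  resid_ok <- if (nrow(pts) >= 4) test_residual_independence(pts, "linear")
              else NULL
  minrow <- find_minimum(atm)
  message("mortality minimum in category '", minrow$label, "'")

  report <- report_row(atm, age_range = cfg$age_range,
                       ci_level = cfg$ci_level, scale = cfg$scale)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_atm(atm, file.path(cfg$out_dir, "atm.csv"), scale = cfg$scale)
    utils::write.csv(report, file.path(cfg$out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(report), file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    message("results written to ", cfg$out_dir)
  }
  invisible(list(atm = atm, points = pts, curvature = curv, fit = fit,
                 inverse = inv, residual_independence = resid_ok,
                 minimum = minrow, report = report))
}
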