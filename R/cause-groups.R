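#' ICD-10 cause-of-death groups
#'
#' Causes of death are coded either by ICD-10 chapter (Roman numerals I-XXII)
#' or by code groups (e.g. "Q03"). A cause group is a named set of chapters
#' and/or code ranges. Predefined groups follow the conventions of pooled
#' childhood-mortality analyses: TOTAL (all chapters), NEOPLASMS (chapter
#' II), OTHER_DISEASES (chapters I-XV without chapter II), and CACNS
#' (congenital anomalies of the central nervous system, a code-level subset
#' of chapter XVII).
#'
#' @name cause-groups
NULL

ICD10_CHAPTERS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                    "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII",
                    "XVIII", "XIX", "XX", "XXI", "XXII")

#' Construct a cause group
#'
#' @param name Group name.
#' @param chapters Character vector of ICD-10 chapter identifiers (Roman
#'   numerals), or NULL.
#' @param code_ranges Character vector of ICD-10 code ranges such as
#'   `"Q00-Q07"` (single codes allowed), or NULL.
#' @return An object of class `"cause_group"`.
#' @export
cause_group <- function(name, chapters = NULL, code_ranges = NULL) {
  if (!is.null(chapters)) {
    bad <- setdiff(chapters, ICD10_CHAPTERS)
    if (length(bad)) stop("unknown ICD-10 chapters: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(list(name = name, chapters = chapters, code_ranges = code_ranges),
            class = "cause_group")
}

#' @export
print.cause_group <- function(x, ...) {
  cat("Cause group:", x$name, "\n")
  if (!is.null(x$chapters)) cat("  chapters:", paste(x$chapters, collapse = ", "), "\n")
  if (!is.null(x$code_ranges)) cat("  code ranges:", paste(x$code_ranges, collapse = ", "), "\n")
  invisible(x)
}

#' Predefined cause groups
#'
#' `cg_total()` keeps every record. `cg_neoplasms()` is chapter II.
#' `cg_other_diseases()` is chapters I-XV with chapter II removed — the
#' aggregate used for deaths not attributed to neoplasms, external causes or
#' the perinatal/congenital chapters. `cg_chapter(ch)` is a single chapter.
#' `cg_cacns()` is the code-level subgroup of chapter XVII for congenital
#' anomalies of the central nervous system; the default code range Q00-Q07
#' is overridable because code lists vary between studies.
#'
#' @param codes Code ranges for CACNS, default `"Q00-Q07"`.
#' @param ch A chapter identifier for `cg_chapter`.
#' @return A `cause_group`.
#' @rdname predefined-groups
#' @export
cg_total <- function() cause_group("TOTAL", chapters = ICD10_CHAPTERS)

#' @rdname predefined-groups
#' @export
cg_neoplasms <- function() cause_group("NEOPLASMS", chapters = "II")

#' @rdname predefined-groups
#' @export
cg_other_diseases <- function() {
  chs <- ICD10_CHAPTERS[1:15]
  cause_group("OTHER_DISEASES", chapters = setdiff(chs, "II"))
}

#' @rdname predefined-groups
#' @export
cg_cacns <- function(codes = "Q00-Q07") cause_group("CACNS", code_ranges = codes)

#' @rdname predefined-groups
#' @export
cg_chapter <- function(ch) cause_group(paste0("CHAPTER_", ch), chapters = ch)

# A cause label is chapter-level if it is a Roman-numeral chapter id;
# otherwise it is treated as an ICD-10 code (letter + digits).
is_chapter_label <- function(x) x %in% ICD10_CHAPTERS

code_in_ranges <- function(codes, ranges) {
  hit <- rep(FALSE, length(codes))
  for (rg in ranges) {
    parts <- strsplit(rg, "-", fixed = TRUE)[[1]]
    lo <- parts[1]
    hi <- if (length(parts) > 1) parts[2] else parts[1]
    # ICD-10 codes compare lexicographically within a letter block (Q00 < Q07)
    hit <- hit | (substr(codes, 1, 3) >= lo & substr(codes, 1, 3) <= hi)
  }
  hit
}

#' Restrict a death-count table to a cause group
#'
#' TOTAL returns the input unchanged. Chapter-based groups keep records
#' whose `cause` is one of the member chapters. Code-range groups require
#' code-level causes in the table; applying one to a chapter-coded table is
#' an error.
#'
#' @param group A `cause_group`.
#' @param table A death-count table (see [load_death_counts()]).
#' @return The filtered table. An empty result triggers a warning, not an
#'   error: zero deaths in a group is meaningful.
#' @export
resolve_cause_group <- function(group, table) {
  stopifnot(inherits(group, "cause_group"))
  if (group$name == "TOTAL") return(table)
  keep <- rep(FALSE, nrow(table))
  if (!is.null(group$chapters)) {
    keep <- keep | (table$cause %in% group$chapters)
  }
  if (!is.null(group$code_ranges)) {
    is_code <- !is_chapter_label(table$cause)
    if (!any(is_code)) {
      stop("cause group '", group$name,
           "' uses code ranges but the table is coded only by chapter: ",
           "code-level data required", call. = FALSE)
    }
    keep[is_code] <- keep[is_code] | code_in_ranges(table$cause[is_code],
                                                   group$code_ranges)
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("cause group '", group$name, "' matched no records", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Load cause-group definitions from YAML or JSON
#'
#' The file maps group names to lists with elements `chapters` and/or
#' `code_ranges`.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @return Named list of `cause_group` objects.
#' @export
load_cause_groups <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- lapply(names(raw), function(nm) {
    cause_group(nm,
                chapters = unlist(raw[[nm]]$chapters),
                code_ranges = unlist(raw[[nm]]$code_ranges))
  })
  names(out) <- names(raw)
  out
}
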