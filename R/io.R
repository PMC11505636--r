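# Cohort CSV I/O. Schema (header required, comma-separated, UTF-8, "" for
# missing): patient_id, age_years, sex, icr_<item_id> x8 (integer level 0-3),
# optional cariogram_chance plus any computed columns. Leading lines starting
# with '#' are provenance comments (seed, config hash) and are skipped on
# read.

cohort_item_cols <- function() paste0("icr_", icr_items())

validate_cohort_rows <- function(df) {
  problems <- list()
  note <- function(row, col, msg)
    problems[[length(problems) + 1]] <<- data.frame(
      row = row, column = col, problem = msg, stringsAsFactors = FALSE)
  for (cn in cohort_item_cols()) {
    v <- df[[cn]]
    bad <- which(is.na(v) | !(v %in% 0:3))
    for (r in bad) note(r, cn, sprintf("item level must be 0..3 (got %s)",
                                       if (is.na(v[r])) "NA" else v[r]))
  }
  if ("cariogram_chance" %in% names(df)) {
    v <- df$cariogram_chance
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    for (r in bad) note(r, "cariogram_chance",
                        sprintf("must lie in [0, 100] (got %s)", v[r]))
  }
  if ("age_years" %in% names(df)) {
    bad <- which(!is.na(df$age_years) & df$age_years < 0)
    for (r in bad) note(r, "age_years", "must be non-negative")
  }
  if (length(problems) == 0) NULL else do.call(rbind, problems)
}

#' Read a cohort CSV
#'
#' Validates the header against the documented schema and every row against
#' the field constraints. Invalid rows are never silently dropped: by default
#' any invalid row aborts the read with a per-row report; with
#' `drop_invalid = TRUE` the offending rows are removed and the report is
#' attached as attribute `"rejected"`.
#'
#' @param path CSV file path.
#' @param drop_invalid drop invalid rows (with a report) instead of erroring.
#' @return cohort data.frame.
#' @export
read_cohort <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) stop_icr(sprintf("cohort file not found: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  required <- c("patient_id", cohort_item_cols())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_icr(sprintf("malformed cohort header; missing columns: %s",
                     paste(missing, collapse = ", ")))
  df$patient_id <- as.character(df$patient_id)
  problems <- validate_cohort_rows(df)
  if (!is.null(problems)) {
    if (!drop_invalid)
      stop_icr(paste0(
        "invalid cohort rows:\n",
        paste(sprintf("  row %d, %s: %s", problems$row, problems$column,
                      problems$problem), collapse = "\n")))
    df <- df[-unique(problems$row), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "rejected") <- problems
  }
  df
}

#' Write a cohort CSV
#'
#' Writes the cohort in the documented schema, preceded by provenance
#' comment lines embedding the package version and, when a config is given,
#' its seed and hash.
#'
#' @param cohort cohort data.frame.
#' @param path destination path.
#' @param config optional [cohort_config()] whose seed and hash are stamped
#'   in the header comment.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  stopifnot(is.data.frame(cohort))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("icrscore"))
  if (!is.null(config))
    writeLines(sprintf("# icrscore %s cohort | seed=%d | config_hash=%s",
                       ver, config$seed, config_hash(config)), con)
  else
    writeLines(sprintf("# icrscore %s cohort", ver), con)
  write.csv(cohort, con, row.names = FALSE, na = "")
  invisible(path)
}
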