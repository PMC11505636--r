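# Cariogram interop: the tool itself outputs a "chance of avoiding caries"
# percentage; analysis here runs on its complement (the risk value) and on
# the three-category risk classification.

#' Cariogram risk category labels (ascending risk)
#' @return character vector: Low, Moderate, High.
#' @export
cariogram_categories <- function() c("Low", "Moderate", "High")

check_chance <- function(chance_avoid) {
  if (length(chance_avoid) == 0 || anyNA(chance_avoid))
    stop_range("chance_avoid contains missing values")
  if (any(chance_avoid < 0 | chance_avoid > 100))
    stop_range("chance_avoid must lie in [0, 100]")
  as.numeric(chance_avoid)
}

#' Complement a chance-of-avoiding-caries percentage into a risk value
#'
#' A Cariogram chance of 33% becomes a risk value of 67%: the two scales are
#' complementary and sum to 100. The transform is its own inverse.
#'
#' @param chance_avoid percentage(s) in \[0, 100\].
#' @return risk percentage(s), `100 - chance_avoid`.
#' @export
complement_risk <- function(chance_avoid) {
  100 - check_chance(chance_avoid)
}

#' Categorize a Cariogram chance value into a risk category
#'
#' Two boundary conventions are supported, both stated on the
#' chance-of-avoiding-caries scale:
#'
#' * `"table"` (default): closed integer bins 0-25 High, 26-75 Moderate,
#'   76-100 Low, extended to non-integer chances by half-unit midpoints
#'   (below 25.5 High, below 75.5 Moderate, otherwise Low).
#' * `"strict"`: chance < 25 High, 25-75 Moderate, > 75 Low.
#'
#' The two differ only at chances of exactly 25 and 75 (and in the open
#' half-unit neighbourhoods around them).
#'
#' @param chance_avoid percentage(s) in \[0, 100\].
#' @param convention `"table"` or `"strict"`.
#' @return character vector of categories (`Low`, `Moderate`, `High`).
#' @export
categorize_cariogram <- function(chance_avoid,
                                 convention = c("table", "strict")) {
  convention <- match.arg(convention)
  chance <- check_chance(chance_avoid)
  if (convention == "table")
    ifelse(chance < 25.5, "High", ifelse(chance < 75.5, "Moderate", "Low"))
  else
    ifelse(chance < 25, "High",
           ifelse(chance <= 75, "Moderate", "Low"))
}

#' Bundle the risk transform and categorization for one patient
#'
#' @param patient_id opaque identifier.
#' @param chance_avoid percentage in \[0, 100\].
#' @param convention boundary convention, see [categorize_cariogram()].
#' @return a `cariogram_assessment`: `patient_id`, `chance_avoid`,
#'   `risk_value`, `category`.
#' @export
cariogram_assess <- function(patient_id, chance_avoid,
                             convention = c("table", "strict")) {
  convention <- match.arg(convention)
  chance <- check_chance(chance_avoid)
  stopifnot(length(chance) == 1L)
  structure(
    list(patient_id = as.character(patient_id),
         chance_avoid = chance,
         risk_value = complement_risk(chance),
         category = categorize_cariogram(chance, convention)),
    class = "cariogram_assessment")
}

#' @export
print.cariogram_assessment <- function(x, ...) {
  cat(sprintf("Cariogram %s: chance to avoid %.1f%%, risk %.1f%% (%s risk)\n",
              if (nzchar(x$patient_id)) x$patient_id else "<unnamed>",
              x$chance_avoid, x$risk_value, x$category))
  invisible(x)
}

#' Assess the Cariogram columns of a cohort table
#'
#' @param cohort data.frame with a `cariogram_chance` column.
#' @param convention boundary convention, see [categorize_cariogram()].
#' @return `cohort` with `cariogram_risk` and `cariogram_category` appended.
#' @export
assess_cohort <- function(cohort, convention = c("table", "strict")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(cohort))
  if (!"cariogram_chance" %in% names(cohort))
    stop_icr("cohort lacks a cariogram_chance column")
  if (anyNA(cohort$cariogram_chance))
    stop_icr(sprintf(
      "cariogram_chance missing for rows: %s",
      paste(which(is.na(cohort$cariogram_chance)), collapse = ", ")))
  cohort$cariogram_risk <- complement_risk(cohort$cariogram_chance)
  cohort$cariogram_category <-
    categorize_cariogram(cohort$cariogram_chance, convention)
  cohort
}
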