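# ICR scoring: per-item points, total score, risk category assignment, and
# mapping of raw clinical measurements onto item levels.

#' Construct a patient record
#'
#' One child's ICR item levels plus optional identifiers and an optional
#' externally computed Cariogram "chance of avoiding caries" percentage.
#'
#' @param patient_id opaque identifier string.
#' @param item_levels named integer vector or list, `item_id -> level 0..3`.
#' @param age_years age in years (study population spans 6-12); optional.
#' @param sex optional label.
#' @param cariogram_chance optional percentage in \[0, 100\].
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, item_levels, age_years = NA_real_,
                           sex = NA_character_, cariogram_chance = NA_real_) {
  item_levels <- unlist(item_levels)
  bad <- setdiff(names(item_levels), icr_items())
  if (length(bad) > 0)
    stop_icr(sprintf("unknown item ids: %s", paste(bad, collapse = ", ")))
  if (any(!is.na(item_levels) & !(item_levels %in% 0:3)))
    stop_icr(sprintf("patient '%s': item levels must be in 0..3", patient_id))
  if (!is.na(cariogram_chance) &&
      (cariogram_chance < 0 || cariogram_chance > 100))
    stop_range(sprintf("patient '%s': cariogram_chance must lie in [0, 100]",
                       patient_id))
  lv <- rep(NA_integer_, 8L)
  names(lv) <- icr_items()
  lv[names(item_levels)] <- as.integer(item_levels)
  structure(
    list(patient_id = as.character(patient_id), age_years = age_years,
         sex = sex, item_levels = lv, cariogram_chance = cariogram_chance),
    class = "patient_record")
}

#' Points awarded by one item at a given level
#'
#' @param item an [item_definition()] object.
#' @param level_index ordinal level, 0 (least cariogenic) to 3.
#' @return integer points.
#' @export
score_item <- function(item, level_index) {
  stopifnot(inherits(item, "icr_item"))
  if (length(level_index) != 1L || is.na(level_index) ||
      !(level_index %in% 0:3))
    stop_icr(sprintf("item '%s': level index must be 0, 1, 2 or 3 (got %s)",
                     item$item_id, paste(level_index, collapse = ",")))
  item$level_points[as.integer(level_index) + 1L]
}

#' Assign the risk category for a total score
#'
#' @param total_score integer total in \[0, maximum\].
#' @param scheme an `icr_scheme`; defaults to [default_scheme()].
#' @return category label (vectorized over `total_score`).
#' @export
categorize_icr <- function(total_score, scheme = default_scheme()) {
  stopifnot(inherits(scheme, "icr_scheme"))
  if (anyNA(total_score)) stop_range("total_score contains missing values")
  if (any(total_score != floor(total_score)))
    stop_range("total_score must be an integer")
  if (any(total_score < 0 | total_score > scheme$max_score))
    stop_range(sprintf("total_score outside [0, %d]", scheme$max_score))
  th <- scheme$thresholds
  idx <- findInterval(total_score, th$min)
  th$label[idx]
}

#' Compute the ICR for one patient record
#'
#' The ICR total is the sum of the eight items' points; the category is the
#' threshold bin containing the total. Records missing any item are rejected:
#' the instrument scores complete questionnaires only, never imputing.
#'
#' @param record a [patient_record()], or a named vector/list of 8 item levels.
#' @param scheme an `icr_scheme`.
#' @return an `icr_result`: list with `patient_id`, `total_score`, `category`.
#' @export
compute_icr <- function(record, scheme = default_scheme()) {
  stopifnot(inherits(scheme, "icr_scheme"))
  if (!inherits(record, "patient_record"))
    record <- patient_record(patient_id = "", item_levels = record)
  lv <- record$item_levels
  missing <- names(lv)[is.na(lv)]
  if (length(missing) > 0)
    stop_icr(sprintf("patient '%s': missing item levels for: %s",
                     record$patient_id, paste(missing, collapse = ", ")))
  total <- 0L
  for (id in icr_items())
    total <- total + score_item(scheme$items[[id]], lv[[id]])
  structure(
    list(patient_id = record$patient_id, total_score = total,
         category = categorize_icr(total, scheme)),
    class = "icr_result")
}

#' @export
print.icr_result <- function(x, ...) {
  cat(sprintf("ICR %s: total %d (%s risk)\n",
              if (nzchar(x$patient_id)) x$patient_id else "<unnamed>",
              x$total_score, x$category))
  invisible(x)
}

#' Score every record of a cohort table
#'
#' @param cohort data.frame with columns `icr_<item_id>` (levels 0-3).
#' @param scheme an `icr_scheme`.
#' @return `cohort` with `icr_total` and `icr_category` columns appended.
#' @export
score_cohort <- function(cohort, scheme = default_scheme()) {
  stopifnot(is.data.frame(cohort), inherits(scheme, "icr_scheme"))
  cols <- paste0("icr_", icr_items())
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0)
    stop_icr(sprintf("cohort lacks item columns: %s",
                     paste(missing, collapse = ", ")))
  lv <- as.matrix(cohort[cols])
  if (anyNA(lv) || any(!(lv %in% 0:3)))
    stop_icr("cohort item levels must be complete and in 0..3")
  pts <- vapply(icr_items(), function(id) {
    scheme$items[[id]]$level_points[lv[, paste0("icr_", id)] + 1L]
  }, integer(nrow(cohort)))
  if (nrow(cohort) == 1L) pts <- matrix(pts, nrow = 1L)
  cohort$icr_total <- as.integer(rowSums(pts))
  cohort$icr_category <- categorize_icr(cohort$icr_total, scheme)
  cohort
}

#' Default raw-measurement mapping rules
#'
#' Cut points used by [map_measurements_to_levels()] to bin raw clinical
#' measurements into item levels. All are configurable; the defaults resolve
#' the ambiguities of the printed level descriptions as follows:
#'
#' * `sugar_breaks`: mean daily sugar exposures; <=1 low, 2-3 moderate,
#'   4-5 high, >5 severe.
#' * `meal_breaks`: meals/snacks per day; 0-3, 4-5, 6-7, >7.
#' * `caries_breaks`: total decayed + restored + missing-due-to-caries count;
#'   the printed level descriptions overlap ("1 or 2", "2 to 4", "4 or more"),
#'   so counts bin as 0; 1-2; 3-4; >=5.
#' * `ph_neutral_tol`: half-width around pH 7 read as "neutral" (litmus strip
#'   resolution); below the neutral band down to 5.5 is "acidic", below 5.5
#'   "critical", above the band "alkaline".
#'
#' @return named list of rule parameters.
#' @export
default_mapping_rules <- function() {
  list(
    sugar_breaks = c(1, 3, 5),     # level k when value <= breaks[k+1]
    meal_breaks = c(3, 5, 7),
    caries_breaks = c(0, 2, 4),
    ph_critical = 5.5,
    ph_neutral_tol = 0.25)
}

bin_by_breaks <- function(value, breaks) {
  # breaks are upper bounds of levels 0..2; above the last -> level 3
  as.integer(findInterval(value, breaks + 1e-9))
}

map_ph <- function(ph, rules) {
  if (is.na(ph) || ph < 0 || ph > 14)
    stop_icr(sprintf("salivary pH outside 0..14: %s", ph))
  lo <- 7 - rules$ph_neutral_tol
  hi <- 7 + rules$ph_neutral_tol
  if (ph < rules$ph_critical) 3L
  else if (ph < lo) 2L
  else if (ph <= hi) 1L
  else 0L
}

map_parent_status <- function(mother, father) {
  ok <- c("-", "+", "++")
  if (!(mother %in% ok) || !(father %in% ok))
    stop_icr(sprintf("parent caries status must be one of -, +, ++ (got %s/%s)",
                     mother, father))
  sev <- c("-" = 0L, "+" = 1L, "++" = 2L)
  hi <- max(sev[[mother]], sev[[father]])
  lo <- min(sev[[mother]], sev[[father]])
  if (hi == 2L && lo == 2L) 3L
  else if (hi == 2L) 2L
  else if (hi == 1L) 1L
  else 0L
}

#' Map raw measurements to ICR item levels
#'
#' Accepts, per item, either a pre-coded level (`icr_<item_id>`) or the raw
#' measurement it derives from, and returns the complete named level vector.
#' Pre-coded levels pass through unchanged; raw values are binned by the
#' configurable `rules`. Items whose level is operator judgment in the clinic
#' (hygiene habits, fluoride program, oral hygiene status) accept an optional
#' raw ordinal (e.g. a Silness-Loe derived plaque grade for
#' `oral_hygiene_status`) but are typically supplied pre-coded.
#'
#' Recognized raw fields: `sugar_exposures_per_day` (diet_content),
#' `meals_per_day` (diet_frequency), `caries_count`, `restorations`,
#' `missing_due_to_caries` (caries_experience), `ph` (ph_test),
#' `mother_status`, `father_status` (family_susceptibility, each one of
#' `-`, `+`, `++`).
#'
#' @param raw named list mixing `icr_<item_id>` levels and raw measurements.
#' @param rules mapping cut points, see [default_mapping_rules()].
#' @return named integer vector of 8 levels (0-3).
#' @export
map_measurements_to_levels <- function(raw, rules = default_mapping_rules()) {
  rules <- modifyList(default_mapping_rules(), rules)
  get_precoded <- function(id) {
    v <- raw[[paste0("icr_", id)]]
    if (is.null(v) || is.na(v)) return(NA_integer_)
    if (!(v %in% 0:3))
      stop_icr(sprintf("pre-coded level for %s must be 0..3 (got %s)", id, v))
    as.integer(v)
  }
  nonneg <- function(field) {
    v <- raw[[field]]
    if (is.null(v) || is.na(v)) return(NULL)
    if (v < 0) stop_icr(sprintf("%s must be non-negative (got %s)", field, v))
    v
  }
  lv <- vapply(icr_items(), get_precoded, integer(1))

  if (is.na(lv[["diet_content"]])) {
    v <- nonneg("sugar_exposures_per_day")
    if (!is.null(v)) lv[["diet_content"]] <- bin_by_breaks(v, rules$sugar_breaks)
  }
  if (is.na(lv[["diet_frequency"]])) {
    v <- nonneg("meals_per_day")
    if (!is.null(v)) lv[["diet_frequency"]] <- bin_by_breaks(v, rules$meal_breaks)
  }
  if (is.na(lv[["caries_experience"]])) {
    parts <- c(nonneg("caries_count"), nonneg("restorations"),
               nonneg("missing_due_to_caries"))
    if (length(parts) > 0)
      lv[["caries_experience"]] <- bin_by_breaks(sum(parts), rules$caries_breaks)
  }
  if (is.na(lv[["ph_test"]])) {
    if (!is.null(raw$ph)) lv[["ph_test"]] <- map_ph(raw$ph, rules)
  }
  if (is.na(lv[["family_susceptibility"]])) {
    if (!is.null(raw$mother_status) && !is.null(raw$father_status))
      lv[["family_susceptibility"]] <-
        map_parent_status(raw$mother_status, raw$father_status)
  }

  missing <- names(lv)[is.na(lv)]
  if (length(missing) > 0)
    stop_icr(sprintf("no level or raw measurement supplied for: %s",
                     paste(missing, collapse = ", ")))
  lv
}
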