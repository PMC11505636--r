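# Scoring scheme: the eight ICR items, their ordinal levels, per-level points
# and the total-score category bins.

#' Canonical ICR item identifiers
#'
#' The eight caries-related factors of the Index of Caries Risk, in the
#' canonical order used throughout the package and in the cohort CSV schema.
#'
#' @return character vector of length 8.
#' @export
icr_items <- function() {
  c("diet_content", "diet_frequency", "hygiene_habits", "fluoride_program",
    "family_susceptibility", "caries_experience", "oral_hygiene_status",
    "ph_test")
}

#' ICR risk category labels
#'
#' @return character vector: Low, Moderate, High, Very High (ascending risk).
#' @export
icr_categories <- function() c("Low", "Moderate", "High", "Very High")

#' Define a single ICR item
#'
#' An item has exactly four ordered levels, from the least to the most
#' cariogenic, each awarding a non-negative, non-decreasing number of points;
#' the least-risky level always awards 0.
#'
#' @param item_id one of [icr_items()].
#' @param level_labels character vector of 4 level descriptions.
#' @param level_points integer vector of 4 points, non-decreasing, starting at 0.
#' @return an object of class `icr_item`.
#' @export
item_definition <- function(item_id, level_labels, level_points = 0:3) {
  if (!is.character(item_id) || length(item_id) != 1L || !item_id %in% icr_items())
    stop_icr(sprintf("unknown item_id '%s'", paste(item_id, collapse = ",")))
  if (length(level_labels) != 4L)
    stop_icr(sprintf("item '%s': exactly 4 level labels required", item_id))
  level_points <- as.integer(level_points)
  if (length(level_points) != 4L || anyNA(level_points))
    stop_icr(sprintf("item '%s': exactly 4 numeric level points required", item_id))
  if (level_points[1] != 0L)
    stop_icr(sprintf("item '%s': points for the lowest level must be 0", item_id))
  if (any(level_points < 0L) || is.unsorted(level_points))
    stop_icr(sprintf("item '%s': level points must be non-negative and non-decreasing", item_id))
  structure(
    list(item_id = item_id,
         level_labels = as.character(level_labels),
         level_points = level_points),
    class = "icr_item")
}

default_item_labels <- function() {
  list(
    diet_content = c(
      "low consumption of sugars",
      "moderate consumption of sugars",
      "high consumption of sugars",
      "severe consumption of sugars"),
    diet_frequency = c(
      "0-3 meals",
      "4-5 meals",
      "6-7 meals",
      "more than 7 meals"),
    hygiene_habits = c(
      "brushing 3 times a day performed by a parent",
      "brushing 2 times a day performed by a parent",
      "brushing 2 times a day with supervision",
      "brushing 1-2 times a day without supervision/no brushing"),
    fluoride_program = c(
      "fluoride toothpaste + fluoride mouthwash + fluoride os (in the past)",
      "fluoride toothpaste + fluoride os (in the past)",
      "fluoride toothpaste",
      "absence of fluoride program"),
    family_susceptibility = c(
      "mother - father -",
      "mother + father -",
      "mother ++ father +/-",
      "mother ++ father ++"),
    caries_experience = c(
      "absence of caries + no old restorations + absence of teeth missing due to caries",
      "1 or 2 caries (or restorations or teeth missing due to caries)",
      "2 to 4 caries (or restorations or teeth missing due to caries)",
      "4 or more caries (or restorations or teeth missing due to caries)"),
    oral_hygiene_status = c(
      "no plaque",
      "plaque without bleeding",
      "plaque with bleeding, calculus, marginal gingivitis",
      "plaque with bleeding, calculus, gingivitis in multiple sites"),
    ph_test = c(
      "alkaline pH (>7)",
      "neutral pH (7)",
      "acidic pH (6.5-5.5)",
      "critical pH (<5.5)"))
}

#' Build a scoring scheme
#'
#' A scheme bundles the eight item definitions with the category thresholds
#' used to bin the total score. Bins must be contiguous, start at 0 and cover
#' the theoretical maximum score.
#'
#' @param items named list of 8 [item_definition()] objects (one per item id).
#' @param thresholds data.frame with columns `label`, `min`, `max` giving the
#'   category bins in ascending score order.
#' @return an object of class `icr_scheme`.
#' @export
scoring_scheme <- function(items, thresholds) {
  ids <- vapply(items, function(it) it$item_id, character(1))
  if (!setequal(ids, icr_items()) || anyDuplicated(ids))
    stop_icr(sprintf(
      "scheme must contain each of the 8 items exactly once; got: %s",
      paste(ids, collapse = ", ")))
  items <- items[match(icr_items(), ids)]
  names(items) <- icr_items()
  max_score <- sum(vapply(items, function(it) it$level_points[4], integer(1)))

  thresholds <- as.data.frame(thresholds, stringsAsFactors = FALSE)
  if (!all(c("label", "min", "max") %in% names(thresholds)))
    stop_icr("thresholds must have columns label, min, max")
  thresholds$min <- as.integer(thresholds$min)
  thresholds$max <- as.integer(thresholds$max)
  thresholds <- thresholds[order(thresholds$min), , drop = FALSE]
  rownames(thresholds) <- NULL
  if (thresholds$min[1] != 0L)
    stop_icr("category bins must start at score 0")
  if (nrow(thresholds) > 1 &&
      any(thresholds$min[-1] != thresholds$max[-nrow(thresholds)] + 1L))
    stop_icr("category bins must be contiguous and non-overlapping")
  if (any(thresholds$max < thresholds$min))
    stop_icr("each category bin needs max >= min")
  if (thresholds$max[nrow(thresholds)] < max_score)
    stop_icr(sprintf("category bins must cover the maximum score (%d)", max_score))

  structure(
    list(items = items, thresholds = thresholds, max_score = max_score),
    class = "icr_scheme")
}

#' The default ICR scoring scheme
#'
#' Each of the eight items awards 0, 1, 2 or 3 points across its four ordered
#' levels (theoretical maximum 24), and total scores are binned as
#' Low 0-5, Moderate 6-10, High 11-15, Very High 16-maximum. The per-item
#' point values and thresholds are fully configurable via [scoring_scheme()]
#' or a scheme config file ([read_scheme()]).
#'
#' @return an `icr_scheme` object.
#' @export
default_scheme <- function() {
  labels <- default_item_labels()
  items <- lapply(icr_items(), function(id)
    item_definition(id, labels[[id]], 0:3))
  max_score <- 8L * 3L
  thresholds <- data.frame(
    label = icr_categories(),
    min = c(0L, 6L, 11L, 16L),
    max = c(5L, 10L, 15L, max_score),
    stringsAsFactors = FALSE)
  scoring_scheme(items, thresholds)
}

#' @export
print.icr_scheme <- function(x, ...) {
  cat(sprintf("ICR scoring scheme: 8 items, maximum score %d\n", x$max_score))
  for (it in x$items)
    cat(sprintf("  %-22s points %s\n", it$item_id,
                paste(it$level_points, collapse = "/")))
  cat("Categories:\n")
  for (i in seq_len(nrow(x$thresholds)))
    cat(sprintf("  %-10s %d-%d\n", x$thresholds$label[i],
                x$thresholds$min[i], x$thresholds$max[i]))
  invisible(x)
}

scheme_to_list <- function(scheme) {
  list(
    items = lapply(scheme$items, function(it)
      list(item_id = it$item_id,
           level_labels = it$level_labels,
           level_points = it$level_points)),
    thresholds = list(
      label = scheme$thresholds$label,
      min = scheme$thresholds$min,
      max = scheme$thresholds$max))
}

scheme_from_list <- function(x) {
  if (is.null(x$items) || is.null(x$thresholds))
    stop_icr("scheme config must contain 'items' and 'thresholds'")
  items <- lapply(x$items, function(it)
    item_definition(it$item_id, unlist(it$level_labels),
                    unlist(it$level_points)))
  th <- x$thresholds
  thresholds <- data.frame(label = unlist(th$label), min = unlist(th$min),
                           max = unlist(th$max), stringsAsFactors = FALSE)
  scoring_scheme(items, thresholds)
}

#' Read or write a scoring-scheme config file
#'
#' Schemes serialize to YAML (`.yml`/`.yaml`) or JSON (`.json`); the format is
#' chosen from the file extension. A reloaded scheme scores identically to
#' the original. The default scheme ships with the package as
#' `system.file("extdata", "icr_scheme.yaml", package = "icrscore")`.
#'
#' @param path file path ending in .yaml, .yml or .json.
#' @param scheme an `icr_scheme` object.
#' @return `read_scheme` returns an `icr_scheme`; `write_scheme` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop_icr(sprintf("scheme file not found: %s", path))
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  scheme_from_list(x)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "icr_scheme"))
  x <- scheme_to_list(scheme)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}
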