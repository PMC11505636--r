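# Method-comparison statistics: descriptive summaries, rounded frequency
# tables, cross-tabulation, Pearson correlation with Fisher-z interval,
# Cohen's kappa (unweighted/weighted) and correlation sample-size planning.

#' Descriptive summary (n, M, SD, min, max)
#'
#' Mean and sample standard deviation (n - 1 denominator) with the range,
#' the summary reported for each risk instrument. A single observation yields
#' `sd = 0` with `degenerate = TRUE` rather than `NA`, keeping pipelines
#' total while flagging that no dispersion was estimable.
#'
#' @param values non-empty numeric vector.
#' @return an `icr_summary`: list with `n`, `mean`, `sd`, `min`, `max`,
#'   `degenerate`.
#' @export
describe <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    stop_icr("describe() needs a non-empty vector without missing values")
  degenerate <- length(values) < 2L
  structure(
    list(n = length(values), mean = mean(values),
         sd = if (degenerate) 0 else sd(values),
         min = min(values), max = max(values), degenerate = degenerate),
    class = "icr_summary")
}

#' @export
print.icr_summary <- function(x, ...) {
  cat(sprintf("n = %d, M = %.2f (SD = %.2f), range %.5g-%.5g%s\n",
              x$n, x$mean, x$sd, x$min, x$max,
              if (x$degenerate) " [degenerate: single observation]" else ""))
  invisible(x)
}

#' One-way frequency table with printed-style percentages
#'
#' Counts each label of an ordered label set and attaches percentages of the
#' total, rounded half away from zero at `decimals` places — the convention
#' that reproduces printed clinical tables (e.g. 8/55 = 14.545% prints as 15%
#' at 0 decimals).
#'
#' @param labels vector of observed labels, all members of `levels`.
#' @param levels ordered label set defining the row order.
#' @param decimals decimal places for the percent column.
#' @return a `freq_table`: data.frame with `label`, `count`, `percent`;
#'   attributes `total` and `decimals`.
#' @export
frequency_table <- function(labels, levels, decimals = 0) {
  bad <- setdiff(unique(labels), levels)
  if (length(bad) > 0)
    stop_icr(sprintf("labels outside the declared set: %s",
                     paste(bad, collapse = ", ")))
  counts <- as.integer(table(factor(labels, levels = levels)))
  total <- length(labels)
  if (total == 0) stop_icr("frequency_table() needs at least one record")
  out <- data.frame(
    label = levels,
    count = counts,
    percent = round_half_away(100 * counts / total, decimals),
    stringsAsFactors = FALSE)
  structure(out, total = total, decimals = decimals,
            class = c("freq_table", "data.frame"))
}

#' Cross-tabulate the two instruments' risk categories
#'
#' Joint category counts with marginal accessors; absent combinations count
#' zero. The row set and column set may differ (four ICR categories against
#' three Cariogram categories).
#'
#' @param row_labels vector of row categories (e.g. ICR), values in
#'   `row_levels`.
#' @param col_labels vector of column categories (e.g. Cariogram), same
#'   length, values in `col_levels`.
#' @param row_levels,col_levels ordered label sets.
#' @return an `icr_crosstab`: integer matrix with `row_marginals`,
#'   `col_marginals` and `total` available via [crosstab_marginals()].
#' @export
cross_tabulate <- function(row_labels, col_labels,
                           row_levels = icr_categories(),
                           col_levels = cariogram_categories()) {
  if (length(row_labels) != length(col_labels))
    stop_icr("row and column label vectors must have equal length")
  bad <- c(setdiff(unique(row_labels), row_levels),
           setdiff(unique(col_labels), col_levels))
  if (length(bad) > 0)
    stop_icr(sprintf("labels outside the declared sets: %s",
                     paste(bad, collapse = ", ")))
  cells <- table(factor(row_labels, levels = row_levels),
                 factor(col_labels, levels = col_levels))
  m <- matrix(as.integer(cells), nrow = length(row_levels),
              dimnames = list(row_levels, col_levels))
  structure(m, class = c("icr_crosstab", "matrix"))
}

#' Marginal totals of a cross-tabulation
#'
#' @param ct an `icr_crosstab`.
#' @return list with `rows` (row sums), `cols` (column sums), `total`.
#' @export
crosstab_marginals <- function(ct) {
  stopifnot(inherits(ct, "icr_crosstab"))
  rows <- rowSums(ct); cols <- colSums(ct)
  list(rows = stats::setNames(as.integer(rows), names(rows)),
       cols = stats::setNames(as.integer(cols), names(cols)),
       total = as.integer(sum(ct)))
}

#' @export
print.icr_crosstab <- function(x, ...) {
  print(unclass(x))
  m <- crosstab_marginals(x)
  cat(sprintf("row totals: %s | column totals: %s | N = %d\n",
              paste(m$rows, collapse = ", "),
              paste(m$cols, collapse = ", "), m$total))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation, two-sided p-value from the t statistic on
#' n - 2 degrees of freedom, and the Fisher-z interval at the requested
#' confidence level (as computed by [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param conf_level confidence level in (0, 1).
#' @return a `correlation_result`: `r`, `n`, `p_value`, `ci_low`, `ci_high`,
#'   `conf_level`.
#' @export
pearson_correlation <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y))
    stop_icr("x and y must have equal length")
  if (length(x) < 3)
    stop_icr("Pearson correlation needs at least 3 paired observations")
  if (anyNA(x) || anyNA(y))
    stop_icr("x and y must not contain missing values")
  if (sd(x) == 0 || sd(y) == 0)
    stop_icr(sprintf("zero variance in %s",
                     paste(c("x", "y")[c(sd(x) == 0, sd(y) == 0)],
                           collapse = " and ")))
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(
    list(r = unname(ct$estimate), n = length(x),
         p_value = ct$p.value,
         ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
         conf_level = conf_level),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("R = %.3f (n = %d, p = %.3g, %g%% CI %.3f to %.3f)\n",
              x$r, x$n, x$p_value, 100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

kappa_weight_matrix <- function(k, weighting) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weighting,
         none = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2)
}

#' Cohen's kappa for two raters on a shared ordered label set
#'
#' Chance-corrected agreement, optionally with linear or quadratic
#' disagreement weights on the ordered labels, and an asymptotic
#' (delta-method) confidence interval; a nonparametric bootstrap interval is
#' available as an alternative. Ratings on different label sets (e.g. the
#' four ICR bins against the three Cariogram bins) are rejected: collapsing
#' categories is a modelling decision the caller must make explicitly.
#'
#' @param rater1,rater2 vectors of ratings, all values in `levels`.
#' @param levels shared ordered label set; defaults to the sorted union of
#'   the observed ratings.
#' @param weighting `"none"` (default), `"linear"` or `"quadratic"`.
#' @param conf_level confidence level for the interval.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param boot_reps bootstrap replicates if `ci = "bootstrap"`.
#' @return an `agreement_result`: `kappa`, `se`, `ci_low`, `ci_high`,
#'   `weighting`, `n`, `p_observed`, `p_expected`.
#' @export
cohens_kappa <- function(rater1, rater2, levels = NULL,
                         weighting = c("none", "linear", "quadratic"),
                         conf_level = 0.95,
                         ci = c("asymptotic", "bootstrap"),
                         boot_reps = 2000) {
  weighting <- match.arg(weighting)
  ci <- match.arg(ci)
  if (length(rater1) != length(rater2))
    stop_icr("the two rating vectors must have equal length")
  n <- length(rater1)
  if (n < 2) stop_icr("kappa needs at least 2 rated subjects")
  if (is.null(levels)) levels <- sort(unique(c(rater1, rater2)))
  bad <- c(setdiff(unique(rater1), levels), setdiff(unique(rater2), levels))
  if (length(bad) > 0)
    stop_icr(sprintf(
      paste("ratings outside the shared label set: %s;",
            "collapse categories explicitly before comparing instruments",
            "with different bins"),
      paste(unique(bad), collapse = ", ")))
  k <- length(levels)
  if (k < 2) stop_icr("kappa needs at least 2 categories in the label set")

  kappa_point <- function(r1, r2) {
    p <- table(factor(r1, levels = levels), factor(r2, levels = levels)) / length(r1)
    w <- kappa_weight_matrix(k, weighting)
    po <- sum(w * p)
    pe <- sum(w * outer(rowSums(p), colSums(p)))
    list(kappa = (po - pe) / (1 - pe), p = p, w = w, po = po, pe = pe)
  }
  fit <- kappa_point(rater1, rater2)
  if (fit$pe >= 1)
    stop_icr("degenerate table: chance agreement is 1 (a rater is constant)")

  # Asymptotic variance of weighted kappa (delta method); reduces to the
  # classical unweighted formula under identity weights.
  p <- fit$p; w <- fit$w; po <- fit$po; pe <- fit$pe
  wr <- as.vector(w %*% colSums(p))   # row-wise expected weights
  wc <- as.vector(rowSums(p) %*% w)   # column-wise expected weights
  term <- (w * (1 - pe) - outer(wr, wc, "+") * (1 - po))^2
  var_k <- (sum(p * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))

  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci == "asymptotic") {
    ci_low <- fit$kappa - z * se
    ci_high <- min(fit$kappa + z * se, 1)
  } else {
    reps <- vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      kappa_point(rater1[idx], rater2[idx])$kappa
    }, numeric(1))
    qs <- quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   na.rm = TRUE, names = FALSE)
    ci_low <- qs[1]; ci_high <- qs[2]
  }
  structure(
    list(kappa = fit$kappa, se = se, ci_low = ci_low, ci_high = ci_high,
         weighting = weighting, n = n, p_observed = po, p_expected = pe,
         conf_level = conf_level, ci_method = ci),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("kappa = %.3f (%s weights, n = %d, %g%% CI %.3f to %.3f, %s)\n",
              x$kappa, x$weighting, x$n, 100 * x$conf_level,
              x$ci_low, x$ci_high, x$ci_method))
  invisible(x)
}

#' Sample size for detecting a correlation
#'
#' Smallest n for which a two-sided test of zero correlation at level `alpha`
#' reaches the requested power when the true correlation is `target_r`, under
#' the Fisher-z approximation with the usual small-sample mean correction
#' (E\[atanh(r)\] ~ atanh(rho) + rho / (2(n - 1))).
#'
#' @param target_r anticipated true correlation, 0 < |r| < 1.
#' @param alpha two-sided significance level.
#' @param power desired power (1 - beta).
#' @return integer sample size.
#' @export
sample_size_for_correlation <- function(target_r, alpha = 0.05, power = 0.80) {
  if (!is.numeric(target_r) || length(target_r) != 1L || is.na(target_r) ||
      abs(target_r) <= 0 || abs(target_r) >= 1)
    stop_icr("target_r must satisfy 0 < |r| < 1")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_icr("alpha and power must lie strictly between 0 and 1")
  r <- abs(target_r)
  z_alpha <- qnorm(1 - alpha / 2)
  achieved <- function(n)
    pnorm(sqrt(n - 3) * (atanh(r) + r / (2 * (n - 1))) - z_alpha)
  n <- 4L
  while (achieved(n) < power) {
    n <- n + 1L
    if (n > 1e7) stop_icr("sample size search did not converge")
  }
  n
}

#' Compare the two instruments across a scored cohort
#'
#' Runs the whole descriptive and concordance bundle on a cohort that carries
#' both instruments' outputs: per-instrument summaries and frequency tables,
#' the merged cross-tabulation, and the Pearson correlation between the ICR
#' total score and the Cariogram risk value (the complement scale).
#'
#' @param cohort data.frame with `icr_total`, `icr_category`,
#'   `cariogram_risk`, `cariogram_category` columns (see [score_cohort()] and
#'   [assess_cohort()]).
#' @param conf_level confidence level for the correlation interval.
#' @param decimals decimal places for the frequency-table percents.
#' @param allow_incomplete drop records missing either instrument instead of
#'   erroring; dropped row numbers are attached as attribute `"excluded"`.
#' @return an `icr_comparison`: list with `n`, `summary_icr`,
#'   `summary_cariogram`, `freq_icr`, `freq_cariogram`, `crosstab`,
#'   `correlation`.
#' @export
compare_cohort <- function(cohort, conf_level = 0.95, decimals = 0,
                           allow_incomplete = FALSE) {
  stopifnot(is.data.frame(cohort))
  needed <- c("icr_total", "icr_category", "cariogram_risk",
              "cariogram_category")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0)
    stop_icr(sprintf(
      "cohort lacks instrument output columns: %s (run score_cohort()/assess_cohort() first)",
      paste(missing_cols, collapse = ", ")))
  incomplete <- which(Reduce(`|`, lapply(cohort[needed], is.na)))
  if (length(incomplete) > 0) {
    if (!allow_incomplete)
      stop_icr(sprintf(
        "records missing an instrument output at rows: %s (set allow_incomplete = TRUE to exclude them)",
        paste(incomplete, collapse = ", ")))
    cohort <- cohort[-incomplete, , drop = FALSE]
  }
  if (nrow(cohort) < 3)
    stop_icr("compare_cohort() needs at least 3 complete records")
  out <- list(
    n = nrow(cohort),
    summary_icr = describe(cohort$icr_total),
    summary_cariogram = describe(cohort$cariogram_risk),
    freq_icr = frequency_table(cohort$icr_category, icr_categories(),
                               decimals),
    freq_cariogram = frequency_table(cohort$cariogram_category,
                                     cariogram_categories(), decimals),
    crosstab = cross_tabulate(cohort$icr_category, cohort$cariogram_category),
    correlation = pearson_correlation(cohort$icr_total,
                                      cohort$cariogram_risk, conf_level))
  if (length(incomplete) > 0) attr(out, "excluded") <- incomplete
  structure(out, class = "icr_comparison")
}
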