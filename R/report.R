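# Report rendering: plain-text tables mirroring the published layout and a
# machine-readable JSON bundle of all statistics.

format_freq_table <- function(ft, title) {
  dec <- attr(ft, "decimals")
  lines <- c(sprintf("%s (N = %d)", title, attr(ft, "total")),
             sprintf("  %-12s %6s %8s", "Risk", "n", "%"))
  for (i in seq_len(nrow(ft)))
    lines <- c(lines, sprintf("  %-12s %6d %8s", ft$label[i], ft$count[i],
                              formatC(ft$percent[i], format = "f",
                                      digits = dec)))
  lines
}

format_crosstab <- function(ct) {
  m <- crosstab_marginals(ct)
  head <- sprintf("  %-12s %s %8s", "ICR \\ Cariogram",
                  paste(sprintf("%10s", colnames(ct)), collapse = ""), "Total")
  body <- vapply(seq_len(nrow(ct)), function(i)
    sprintf("  %-15s %s %8d", rownames(ct)[i],
            paste(sprintf("%10d", ct[i, ]), collapse = ""), m$rows[i]),
    character(1))
  foot <- sprintf("  %-15s %s %8d", "Total",
                  paste(sprintf("%10d", m$cols), collapse = ""), m$total)
  c("Merged caries risk cross-tabulation", head, body, foot)
}

#' Render a comparison as plain-text tables
#'
#' @param x an `icr_comparison` (from [compare_cohort()]) or `icr_study`.
#' @return character vector of report lines, invisibly printed by the
#'   corresponding `print` methods.
#' @export
render_report <- function(x) {
  if (inherits(x, "icr_study")) {
    header <- sprintf("Simulated comparative study: %d enrolled, %d analyzed",
                      x$n_enrolled, x$n_analyzed)
    return(c(header, render_report(x$comparison)))
  }
  stopifnot(inherits(x, "icr_comparison"))
  si <- x$summary_icr; sc <- x$summary_cariogram; co <- x$correlation
  c(format_freq_table(x$freq_cariogram, "Caries risk by Cariogram"),
    "",
    format_freq_table(x$freq_icr, "Caries risk by ICR"),
    "",
    format_crosstab(x$crosstab),
    "",
    sprintf("Cariogram risk: M = %.1f (SD = %.1f), range %.5g-%.5g",
            sc$mean, sc$sd, sc$min, sc$max),
    sprintf("ICR total:      M = %.1f (SD = %.1f), range %.5g-%.5g",
            si$mean, si$sd, si$min, si$max),
    sprintf("Pearson R = %.2f (n = %d, p = %.3g, %g%% CI %.2f to %.2f)",
            co$r, co$n, co$p_value, 100 * co$conf_level, co$ci_low,
            co$ci_high))
}

#' @export
print.icr_comparison <- function(x, ...) {
  writeLines(render_report(x))
  invisible(x)
}

comparison_to_list <- function(x) {
  sum_list <- function(s) s[c("n", "mean", "sd", "min", "max", "degenerate")]
  ft_list <- function(ft) list(label = ft$label, count = ft$count,
                               percent = ft$percent,
                               total = attr(ft, "total"),
                               decimals = attr(ft, "decimals"))
  list(
    n = x$n,
    summary_icr = sum_list(x$summary_icr),
    summary_cariogram = sum_list(x$summary_cariogram),
    freq_icr = ft_list(x$freq_icr),
    freq_cariogram = ft_list(x$freq_cariogram),
    crosstab = list(rows = rownames(x$crosstab),
                    cols = colnames(x$crosstab),
                    cells = unclass(x$crosstab)),
    correlation = x$correlation[c("r", "n", "p_value", "ci_low", "ci_high",
                                  "conf_level")])
}

#' Write or read the machine-readable statistics bundle
#'
#' `write_stats_json()` serializes a comparison (or emulated study) to JSON;
#' `render_stats_json()` re-renders a saved bundle as the plain-text tables.
#'
#' @param x an `icr_comparison` or `icr_study`.
#' @param path JSON path.
#' @return `write_stats_json` returns `path` invisibly;
#'   `render_stats_json` returns the report lines.
#' @export
write_stats_json <- function(x, path) {
  out <- if (inherits(x, "icr_study"))
    c(list(n_enrolled = x$n_enrolled, n_analyzed = x$n_analyzed,
           seed = x$config$seed, slope = x$slope,
           config_hash = config_hash(x$config)),
      comparison_to_list(x$comparison))
  else comparison_to_list(x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_stats_json
#' @export
render_stats_json <- function(path) {
  if (!file.exists(path)) stop_icr(sprintf("stats file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ft <- function(f) structure(
    data.frame(label = f$label, count = f$count, percent = f$percent,
               stringsAsFactors = FALSE),
    total = f$total, decimals = f$decimals,
    class = c("freq_table", "data.frame"))
  cells <- matrix(as.integer(x$crosstab$cells),
                  nrow = length(x$crosstab$rows),
                  dimnames = list(x$crosstab$rows, x$crosstab$cols))
  comp <- structure(
    list(n = x$n,
         summary_icr = structure(x$summary_icr, class = "icr_summary"),
         summary_cariogram = structure(x$summary_cariogram,
                                       class = "icr_summary"),
         freq_icr = ft(x$freq_icr),
         freq_cariogram = ft(x$freq_cariogram),
         crosstab = structure(cells, class = c("icr_crosstab", "matrix")),
         correlation = structure(x$correlation,
                                 class = "correlation_result")),
    class = "icr_comparison")
  lines <- render_report(comp)
  if (!is.null(x$n_analyzed))
    lines <- c(sprintf("Simulated comparative study: %d enrolled, %d analyzed",
                       x$n_enrolled, x$n_analyzed), lines)
  lines
}
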