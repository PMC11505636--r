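# Shared fixtures: random records/cohorts built in code, plus the independent
# oracles used across tests.

random_levels <- function() {
  v <- sample(0:3, 8, replace = TRUE)
  names(v) <- icr_items()
  v
}

random_cohort <- function(n, with_chance = TRUE) {
  lv <- matrix(sample(0:3, 8 * n, replace = TRUE), nrow = n,
               dimnames = list(NULL, paste0("icr_", icr_items())))
  out <- data.frame(patient_id = sprintf("R%03d", seq_len(n)),
                    age_years = sample(6:12, n, replace = TRUE),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(lv))
  if (with_chance) out$cariogram_chance <- round(runif(n, 0, 100), 4)
  out
}

# Brute-force ICR total: direct point lookup and summation, independent of
# compute_icr's path.
brute_force_total <- function(levels, scheme) {
  tot <- 0
  for (id in names(levels))
    tot <- tot + scheme$items[[id]]$level_points[levels[[id]] + 1]
  tot
}

# Monte-Carlo power of the two-sided t-test of zero correlation.
mc_power <- function(n, rho, reps = 10000, alpha = 0.05) {
  x <- matrix(rnorm(n * reps), nrow = n)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * reps), nrow = n)
  cx <- sweep(x, 2, colMeans(x))
  cy <- sweep(y, 2, colMeans(y))
  r <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  mean(p < alpha)
}

# Smallest n whose Monte-Carlo power reaches `power`, scanned around a hint.
mc_sample_size <- function(rho, hint, reps = 10000, alpha = 0.05,
                           power = 0.80) {
  for (n in seq(max(4, hint - 3), hint + 4)) {
    if (mc_power(n, rho, reps = reps, alpha = alpha) >= power) return(n)
  }
  Inf
}

# The seven nonzero cells of the published merged cross-tabulation, expanded
# to per-child category pairs.
published_merged_pairs <- function() {
  cells <- rbind(
    c("Low", "Low", 8),
    c("Moderate", "Low", 7),
    c("Moderate", "Moderate", 18),
    c("Moderate", "High", 3),
    c("High", "Moderate", 3),
    c("High", "High", 9),
    c("Very High", "High", 7))
  data.frame(
    icr = rep(cells[, 1], times = as.integer(cells[, 3])),
    cariogram = rep(cells[, 2], times = as.integer(cells[, 3])),
    stringsAsFactors = FALSE)
}
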