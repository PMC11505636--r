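# Synthetic pediatric cohorts: one-factor Gaussian-copula ordinal items with
# configurable marginals, a Cariogram chance value coupled to the same latent
# risk, and a dropout process. Everything is driven by one root seed with
# independent substreams per stage.

#' Default per-item marginal level distributions
#'
#' The observed level proportions of the eight ICR items in a 55-child
#' pediatric cohort, used as the simulator's default marginals.
#'
#' @return named list of 8 probability vectors (length 4, each summing to 1).
#' @export
default_item_marginals <- function() {
  lapply(list(
    diet_content = c(2, 19, 22, 12),
    diet_frequency = c(3, 35, 10, 7),
    hygiene_habits = c(2, 3, 10, 40),
    fluoride_program = c(0, 0, 54, 1),
    family_susceptibility = c(16, 11, 16, 12),
    caries_experience = c(22, 8, 7, 18),
    oral_hygiene_status = c(8, 26, 14, 7),
    ph_test = c(34, 20, 0, 1)), function(x) x / sum(x))
}

#' Simulator configuration
#'
#' Parameters of the synthetic-cohort generator. Each child carries a latent
#' standard-normal risk factor L; item j is the ordinal probit cut of
#' `loading[j] * L + sqrt(1 - loading[j]^2) * noise` at thresholds chosen so
#' the item's marginal law matches `marginals[[j]]`, and the Cariogram chance
#' of avoiding caries is `100 * pnorm(-(cariogram_slope * L + cariogram_noise_sd * noise))`.
#'
#' @param n_enrolled number of children enrolled before dropout.
#' @param seed root seed; all stage substreams derive from it.
#' @param marginals per-item level probabilities
#'   (default [default_item_marginals()]).
#' @param loading latent-factor loading(s) in \[0, 1): scalar or one per item.
#' @param cariogram_slope coupling of latent risk to the Cariogram value.
#' @param cariogram_noise_sd sd of the Cariogram-specific noise.
#' @param target_corr optional target Pearson correlation between ICR total
#'   and Cariogram risk; used by [calibrate_coupling()] and by
#'   [emulate_study()] when `cariogram_slope` is `NULL`.
#' @param dropout_prob per-child probability of failing to attend the second
#'   visit.
#' @param dropout_count optional exact number of dropouts; takes precedence
#'   over `dropout_prob` when not `NULL` (the emulated study loses exactly
#'   14 of 69).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_enrolled = 69, seed = 1,
                          marginals = default_item_marginals(),
                          loading = 0.8,
                          cariogram_slope = 1.0,
                          cariogram_noise_sd = 0.3,
                          target_corr = 0.88,
                          dropout_prob = 14 / 69,
                          dropout_count = 14) {
  if (!is_count(n_enrolled)) stop_icr("n_enrolled must be a non-negative integer")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_icr("seed must be a single integer")
  if (!is.list(marginals) || !setequal(names(marginals), icr_items()))
    stop_icr("marginals must be a named list covering all 8 items")
  for (id in icr_items()) {
    m <- marginals[[id]]
    if (length(m) != 4L || anyNA(m) || any(m < 0) || any(m > 1) ||
        abs(sum(m) - 1) > 1e-9)
      stop_icr(sprintf(
        "marginals for '%s' must be 4 probabilities summing to 1", id))
  }
  loading <- rep_len(as.numeric(loading), 8L)
  names(loading) <- icr_items()
  if (any(loading < 0 | loading >= 1))
    stop_icr("loadings must lie in [0, 1)")
  if (!is.null(cariogram_slope) &&
      (!is.numeric(cariogram_slope) || cariogram_slope < 0))
    stop_icr("cariogram_slope must be non-negative or NULL")
  if (cariogram_noise_sd < 0) stop_icr("cariogram_noise_sd must be >= 0")
  if (!is.null(target_corr) && (target_corr < 0 || target_corr >= 1))
    stop_icr("target_corr must lie in [0, 1)")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop_icr("dropout_prob must lie in [0, 1)")
  if (!is.null(dropout_count) && !is_count(dropout_count))
    stop_icr("dropout_count must be a non-negative integer or NULL")
  structure(
    list(n_enrolled = as.integer(n_enrolled), seed = as.integer(seed),
         marginals = marginals[icr_items()], loading = loading,
         cariogram_slope = cariogram_slope,
         cariogram_noise_sd = cariogram_noise_sd,
         target_corr = target_corr,
         dropout_prob = dropout_prob,
         dropout_count = if (is.null(dropout_count)) NULL
                         else as.integer(dropout_count)),
    class = "cohort_config")
}

config_hash <- function(config) {
  string_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA))
}

# Probit thresholds for a 4-level marginal; -Inf entries encode levels of
# probability zero.
marginal_thresholds <- function(m) qnorm(pmin(cumsum(m)[1:3], 1))

# Core sampler on pre-drawn latent factors; shared by generate_cohort and
# the common-random-numbers path of calibrate_coupling.
draw_items <- function(L, config) {
  n <- length(L)
  lv <- matrix(0L, nrow = n, ncol = 8L,
               dimnames = list(NULL, paste0("icr_", icr_items())))
  for (j in seq_along(icr_items())) {
    id <- icr_items()[j]
    lam <- config$loading[[id]]
    z <- lam * L + sqrt(1 - lam^2) * rnorm(n)
    lv[, j] <- findInterval(z, marginal_thresholds(config$marginals[[id]]))
  }
  lv
}

#' Generate a synthetic cohort
#'
#' Draws `n_enrolled` children under the one-factor copula model of
#' [cohort_config()]: correlated ordinal item levels with the configured
#' marginals, a Cariogram chance value monotonically decreasing in the
#' latent risk, integer ages uniform on 6-12 and balanced sex. Deterministic
#' given the config seed.
#'
#' @param config a [cohort_config()].
#' @return data.frame in the cohort CSV schema: `patient_id`, `age_years`,
#'   `sex`, the eight `icr_<item_id>` level columns and `cariogram_chance`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_enrolled
  if (is.null(config$cariogram_slope))
    stop_icr("config has no cariogram_slope; run calibrate_coupling() first")
  cols <- c("patient_id", "age_years", "sex",
            paste0("icr_", icr_items()), "cariogram_chance")
  if (n == 0L) {
    out <- data.frame(patient_id = character(0), age_years = integer(0),
                      sex = character(0))
    for (cn in paste0("icr_", icr_items())) out[[cn]] <- integer(0)
    out$cariogram_chance <- numeric(0)
    return(out)
  }
  with_seed(substream_seed(config$seed, "generate"), {
    L <- rnorm(n)
    lv <- draw_items(L, config)
    chance <- pmin(pmax(
      100 * pnorm(-(config$cariogram_slope * L +
                      config$cariogram_noise_sd * rnorm(n))), 0), 100)
    sex <- sample(rep_len(c("F", "M"), n))
    age <- sample(6:12, n, replace = TRUE)
    out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      age_years = age, sex = sex, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(lv))
    out$cariogram_chance <- chance
    out <- out[cols]
    # diagnostic: the latent risk factor behind each child's draws
    attr(out, "latent") <- L
    out
  })
}

#' Calibrate the Cariogram coupling slope to a target correlation
#'
#' Finds the slope at which the Pearson correlation between the ICR total
#' score and the Cariogram risk value, in a large simulated cohort, matches
#' `target_corr`. A common set of random draws is shared across slope
#' evaluations, making the achieved correlation a smooth, deterministic
#' function of the slope; the search brackets on a coarse grid and bisects on
#' the rising branch. Targets above the model's correlation ceiling (imposed
#' by item discreteness and the loadings) raise an infeasibility error that
#' reports the achievable maximum.
#'
#' @param config a [cohort_config()].
#' @param target_corr target correlation in \[0, 1); defaults to
#'   `config$target_corr`.
#' @param tol bisection tolerance on the achieved correlation.
#' @param n_calibration simulated cohort size used during the search.
#' @return the calibrated slope, with attributes `achieved_corr` and
#'   `n_calibration`.
#' @export
calibrate_coupling <- function(config = cohort_config(),
                               target_corr = config$target_corr,
                               tol = 0.005, n_calibration = 100000) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(target_corr) || target_corr < 0 || target_corr >= 1)
    stop_icr("target_corr must lie in [0, 1)")
  if (target_corr == 0)
    return(structure(0, achieved_corr = 0, n_calibration = n_calibration))

  draws <- with_seed(substream_seed(config$seed, "calibrate"), {
    L <- rnorm(n_calibration)
    tot <- rowSums(draw_items(L, config))
    eta <- rnorm(n_calibration)
    list(L = L, tot = tot, eta = eta)
  })
  achieved <- function(slope) {
    risk <- 100 - pmin(pmax(
      100 * pnorm(-(slope * draws$L + config$cariogram_noise_sd * draws$eta)),
      0), 100)
    cor(draws$tot, risk)
  }
  grid <- seq(0.05, 4, by = 0.05)
  vals <- vapply(grid, achieved, numeric(1))
  imax <- which.max(vals)
  if (target_corr > vals[imax] - tol)
    stop_icr(sprintf(
      "target correlation %.3f exceeds the achievable maximum %.3f under these marginals and loadings",
      target_corr, vals[imax]))
  lo <- 0; hi <- grid[imax]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- achieved(mid)
    if (abs(v - target_corr) < tol / 2) break
    if (v < target_corr) lo <- mid else hi <- mid
  }
  structure(mid, achieved_corr = achieved(mid),
            n_calibration = n_calibration)
}

#' Remove a random dropout subset from a cohort
#'
#' Emulates loss to follow-up (failure to attend the second visit for the
#' salivary tests). With `dropout_count` given, exactly that many children
#' are removed; otherwise each child independently drops out with probability
#' `dropout_prob`.
#'
#' @param cohort cohort data.frame.
#' @param dropout_prob per-child dropout probability.
#' @param dropout_count exact number of dropouts (takes precedence).
#' @param seed seed for the dropout draw.
#' @return the retained cohort; dropped row count attached as attribute
#'   `"n_dropped"`.
#' @export
apply_dropout <- function(cohort, dropout_prob = NULL, dropout_count = NULL,
                          seed = 1) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  if (!is.null(dropout_count)) {
    if (!is_count(dropout_count)) stop_icr("dropout_count must be a non-negative integer")
    if (dropout_count > n)
      stop_icr(sprintf("dropout_count (%d) exceeds cohort size (%d)",
                       dropout_count, n))
    drop_idx <- with_seed(substream_seed(seed, "dropout"),
                          sort(sample.int(n, dropout_count)))
  } else {
    if (is.null(dropout_prob) || dropout_prob < 0 || dropout_prob >= 1)
      stop_icr("supply dropout_count or a dropout_prob in [0, 1)")
    drop_idx <- with_seed(substream_seed(seed, "dropout"),
                          which(runif(n) < dropout_prob))
  }
  out <- if (length(drop_idx) > 0) cohort[-drop_idx, , drop = FALSE] else cohort
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(drop_idx)
  out
}

#' Emulate the full comparative study on a synthetic cohort
#'
#' Runs the whole pipeline: generate the enrolled cohort, apply dropout,
#' score the ICR, assess the Cariogram values, and compute the comparison
#' bundle (summaries, frequency tables, merged cross-tabulation, Pearson
#' correlation). If the config carries no coupling slope, it is first
#' calibrated to `config$target_corr`.
#'
#' @param config a [cohort_config()].
#' @param scheme scoring scheme for the ICR.
#' @param convention Cariogram boundary convention.
#' @param conf_level confidence level for the correlation interval.
#' @return an `icr_study`: list with `config`, `slope`, `n_enrolled`,
#'   `n_analyzed`, `cohort` (the analyzed, fully scored table) and
#'   `comparison` (an `icr_comparison`).
#' @export
emulate_study <- function(config = cohort_config(), scheme = default_scheme(),
                          convention = c("table", "strict"),
                          conf_level = 0.95) {
  convention <- match.arg(convention)
  stopifnot(inherits(config, "cohort_config"))
  slope <- config$cariogram_slope
  if (is.null(slope)) {
    slope <- calibrate_coupling(config)
    config$cariogram_slope <- as.numeric(slope)
  }
  cohort <- generate_cohort(config)
  analyzed <- apply_dropout(cohort, dropout_prob = config$dropout_prob,
                            dropout_count = config$dropout_count,
                            seed = config$seed)
  analyzed <- score_cohort(analyzed, scheme)
  analyzed <- assess_cohort(analyzed, convention)
  structure(
    list(config = config, slope = as.numeric(slope),
         n_enrolled = nrow(cohort), n_analyzed = nrow(analyzed),
         cohort = analyzed,
         comparison = compare_cohort(analyzed, conf_level = conf_level)),
    class = "icr_study")
}

#' @export
print.icr_study <- function(x, ...) {
  cat(sprintf("Simulated comparative study: %d enrolled, %d analyzed\n",
              x$n_enrolled, x$n_analyzed))
  print(x$comparison)
  invisible(x)
}
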