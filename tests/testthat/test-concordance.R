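test_that("descriptive summaries use the n-1 standard deviation", {
  s <- describe(c(5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_false(s$degenerate)

  s <- describe(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 1.2909944, tolerance = 1e-6)  # sqrt(5/3), hand computed
  expect_equal(s$min, 1)
  expect_equal(s$max, 4)

  s <- describe(7)
  expect_equal(s$sd, 0)
  expect_true(s$degenerate)

  expect_error(describe(numeric(0)), class = "icr_validation_error")
})

test_that("percent rounding goes half away from zero", {
  expect_equal(round_half_away(14.545, 0), 15)
  expect_equal(round_half_away(34.545, 0), 35)
  expect_equal(round_half_away(14.545, 1), 14.5)
  expect_equal(round_half_away(-2.5, 0), -3)
  expect_equal(round_half_away(2.5, 0), 3)
})

test_that("frequency tables reproduce printed-style percentages", {
  labs <- c(rep("High", 19), rep("Moderate", 21), rep("Low", 15))
  ft <- frequency_table(labs, c("High", "Moderate", "Low"))
  expect_identical(ft$count, c(19L, 21L, 15L))
  expect_equal(ft$percent, c(35, 38, 27))
  expect_identical(attr(ft, "total"), 55L)

  labs <- c(rep("Very High", 7), rep("High", 12), rep("Moderate", 28),
            rep("Low", 8))
  ft <- frequency_table(labs, c("Very High", "High", "Moderate", "Low"))
  expect_equal(ft$percent, c(13, 22, 51, 15))

  ft <- frequency_table(rep("c", 55), c("a", "b", "c"))
  expect_equal(ft$percent, c(0, 0, 100))
  expect_equal(sum(ft$count), attr(ft, "total"))

  expect_error(frequency_table(c("a", "d"), c("a", "b")),
               class = "icr_validation_error")

  # percents stay within half a unit of the exact fraction
  set.seed(31)
  for (i in 1:50) {
    labs <- sample(letters[1:4], sample(5:200, 1), replace = TRUE)
    dec <- sample(0:2, 1)
    ft <- frequency_table(labs, letters[1:4], decimals = dec)
    exact <- 100 * ft$count / attr(ft, "total")
    expect_true(all(abs(ft$percent - exact) <= 0.5 * 10^(-dec) + 1e-12))
  }
})

test_that("cross-tabulation counts match a brute-force dictionary", {
  set.seed(41)
  icr <- sample(icr_categories(), 200, replace = TRUE)
  cg <- sample(cariogram_categories(), 200, replace = TRUE)
  ct <- cross_tabulate(icr, cg)
  for (r in icr_categories())
    for (c in cariogram_categories())
      expect_identical(ct[r, c], sum(icr == r & cg == c))
  m <- crosstab_marginals(ct)
  expect_identical(unname(m$total), 200L)
  # marginals reconcile with one-way frequency tables on the same records
  expect_equal(unname(m$rows),
               frequency_table(icr, icr_categories())$count)
  expect_equal(unname(m$cols),
               frequency_table(cg, cariogram_categories())$count)

  ct1 <- cross_tabulate(rep("Low", 9), rep("High", 9))
  expect_identical(sum(ct1 > 0), 1L)
  expect_identical(ct1["Low", "High"], 9L)

  expect_error(cross_tabulate("Extreme", "Low"),
               class = "icr_validation_error")
})

test_that("Pearson correlation matches hand-computed oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  # covariance 8/4, variances 10/4 and 10/4 -> r = 8/10
  res <- pearson_correlation(x, c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  expect_true(res$p_value >= 0 && res$p_value <= 1)

  err <- expect_error(pearson_correlation(x, rep(2, 5)),
                      class = "icr_validation_error")
  expect_match(conditionMessage(err), "y")
  expect_error(pearson_correlation(1:2, 1:2), class = "icr_validation_error")
})

test_that("Pearson correlation is symmetric and affine-equivariant", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- rnorm(30)
    r <- pearson_correlation(x, y)$r
    expect_equal(pearson_correlation(y, x)$r, r)
    expect_equal(pearson_correlation(3 * x + 2, 0.5 * y - 1)$r, r)
    expect_equal(pearson_correlation(-2 * x, y)$r, -r)
  }
})

test_that("kappa reproduces hand-computed agreement oracles", {
  # perfect agreement
  r1 <- rep(c("a", "b", "c"), times = c(5, 7, 9))
  expect_equal(cohens_kappa(r1, r1)$kappa, 1)

  # 2x2 table (20, 5; 10, 15): p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  r1 <- rep(c("x", "x", "y", "y"), times = c(20, 5, 10, 15))
  r2 <- rep(c("x", "y", "x", "y"), times = c(20, 5, 10, 15))
  fit <- cohens_kappa(r1, r2)
  expect_equal(fit$kappa, 0.4)
  expect_equal(fit$p_observed, 0.7)
  expect_equal(fit$p_expected, 0.5)
  expect_true(fit$ci_low <= 0.4 && 0.4 <= fit$ci_high)

  # independent-by-construction product table -> kappa = 0
  r1 <- rep(c("x", "x", "y", "y"), times = c(6, 14, 9, 21))
  r2 <- rep(c("x", "y", "x", "y"), times = c(6, 14, 9, 21))
  expect_equal(cohens_kappa(r1, r2)$kappa, 0)
})

test_that("quadratic weights on two categories equal unweighted kappa", {
  set.seed(61)
  r1 <- sample(c("lo", "hi"), 80, replace = TRUE)
  r2 <- ifelse(runif(80) < 0.7, r1, sample(c("lo", "hi"), 80, replace = TRUE))
  lv <- c("lo", "hi")
  k_none <- cohens_kappa(r1, r2, lv)$kappa
  expect_equal(cohens_kappa(r1, r2, lv, weighting = "quadratic")$kappa, k_none)
  expect_equal(cohens_kappa(r1, r2, lv, weighting = "linear")$kappa, k_none)
})

test_that("unweighted kappa agrees with an independent implementation", {
  set.seed(71)
  lv <- c("Low", "Moderate", "High")
  r1 <- sample(lv, 120, replace = TRUE)
  r2 <- ifelse(runif(120) < 0.6, r1, sample(lv, 120, replace = TRUE))
  ours <- cohens_kappa(r1, r2, lv)$kappa
  cm <- caret::confusionMatrix(factor(r2, lv), factor(r1, lv))
  expect_equal(ours, unname(cm$overall["Kappa"]), tolerance = 1e-10)
})

test_that("ratings outside the shared label set are rejected", {
  expect_error(
    cohens_kappa(c("Low", "Very High"), c("Low", "High"),
                 levels = cariogram_categories()),
    "collapse", class = "icr_validation_error")
  expect_error(cohens_kappa("a", "a"), class = "icr_validation_error")
})

test_that("bootstrap kappa interval brackets the point estimate", {
  set.seed(81)
  lv <- c("lo", "mid", "hi")
  r1 <- sample(lv, 60, replace = TRUE)
  r2 <- ifelse(runif(60) < 0.6, r1, sample(lv, 60, replace = TRUE))
  fit <- cohens_kappa(r1, r2, lv, ci = "bootstrap", boot_reps = 500)
  expect_true(fit$ci_low <= fit$kappa && fit$kappa <= fit$ci_high)
})

test_that("correlation sample sizes match their Monte-Carlo oracle", {
  # frozen expected values, confirmed by mc_sample_size below
  expect_identical(sample_size_for_correlation(0.7), 13L)
  expect_identical(sample_size_for_correlation(0.5), 29L)

  set.seed(91)
  for (rho in c(0.5, 0.7)) {
    n_cf <- sample_size_for_correlation(rho)
    n_mc <- mc_sample_size(rho, hint = n_cf, reps = 10000)
    expect_lte(abs(n_cf - n_mc), 1)
  }

  # required n shrinks as the anticipated correlation grows
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), sample_size_for_correlation,
                  integer(1))
  expect_true(all(diff(sizes) < 0))

  expect_error(sample_size_for_correlation(0), class = "icr_validation_error")
  expect_error(sample_size_for_correlation(1), class = "icr_validation_error")
  expect_error(sample_size_for_correlation(0.5, alpha = 0),
               class = "icr_validation_error")
})

test_that("compare_cohort reproduces a hand-computed three-record bundle", {
  cohort <- data.frame(
    patient_id = c("a", "b", "c"),
    icr_total = c(4L, 9L, 17L),
    icr_category = c("Low", "Moderate", "Very High"),
    cariogram_risk = c(20, 50, 90),
    cariogram_category = c("Low", "Moderate", "High"),
    stringsAsFactors = FALSE)
  comp <- compare_cohort(cohort)
  expect_equal(comp$summary_icr$mean, 10)           # (4+9+17)/3
  expect_equal(comp$summary_icr$sd, sqrt(43))  # deviations -6,-1,7 -> var 86/2
  expect_equal(comp$summary_cariogram$mean, 160/3)
  expect_identical(unname(crosstab_marginals(comp$crosstab)$total), 3L)
  expect_identical(comp$crosstab["Low", "Low"], 1L)
  expect_identical(comp$crosstab["Moderate", "Moderate"], 1L)
  expect_identical(comp$crosstab["Very High", "High"], 1L)
  # r for (4,9,17) vs (20,50,90): hand computation
  xc <- c(4, 9, 17) - 10; yc <- c(20, 50, 90) - 160/3
  r_hand <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  expect_equal(comp$correlation$r, r_hand)
})

test_that("an affine Cariogram risk gives r = 1 and incomplete rows are policed", {
  set.seed(111)
  cohort <- score_cohort(random_cohort(40, with_chance = FALSE))
  cohort$cariogram_risk <- 4 * cohort$icr_total
  cohort$cariogram_category <- "Moderate"
  expect_equal(compare_cohort(cohort)$correlation$r, 1)

  cohort$cariogram_risk[c(3, 8)] <- NA
  err <- expect_error(compare_cohort(cohort), class = "icr_validation_error")
  expect_match(conditionMessage(err), "3, 8")
  comp <- compare_cohort(cohort, allow_incomplete = TRUE)
  expect_identical(comp$n, 38L)
  expect_identical(attr(comp, "excluded"), c(3L, 8L))

  expect_error(compare_cohort(cohort[, c("patient_id", "icr_total")]),
               class = "icr_validation_error")
})
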