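# build a case-control cohort with an arbitrary extra predictor column
assoc_cohort <- function(exposure, is_case, ancestry = "European") {
  rows <- lapply(seq_along(exposure), function(i) {
    toy_subject(sprintf("S%04d", i), ancestry = ancestry,
                status = if (is_case[i]) "invasive" else "control")
  })
  ch <- toy_cohort(rows)
  ch$x <- exposure
  ch
}

test_that("the logistic OR on a binary covariate equals the 2x2 cross-product ratio", {
  exposure <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  is_case <- c(rep(TRUE, 100), rep(FALSE, 100))
  ch <- assoc_cohort(exposure, is_case)
  st <- stratum_spec("European", "invasive", "all")
  res <- fit_association(ch, "x", st, risk_unit = "raw")
  expect_equal(unname(res$or), (10 * 95) / (90 * 5), tolerance = 1e-6)
  expect_equal(res$n_cases, 100)
  expect_equal(res$n_controls, 100)
  expect_true(res$or_ci[1, 1] < res$or & res$or < res$or_ci[1, 2])
})

test_that("degenerate and collinear fits are flagged, never silent", {
  ch <- assoc_cohort(rep(1, 40), rep(c(TRUE, FALSE), 20))
  st <- stratum_spec("European", "invasive", "all")
  res <- fit_association(ch, "x", st, risk_unit = "raw")
  expect_true("rank_deficient" %in% res$flags ||
                "separation" %in% res$flags)
  # perfect separation
  ch2 <- assoc_cohort(c(rep(1, 20), rep(0, 20)),
                      c(rep(TRUE, 20), rep(FALSE, 20)))
  res2 <- fit_association(ch2, "x", st, risk_unit = "raw")
  expect_true("separation" %in% res2$flags)
  # two identical predictors -> rank deficiency
  ch3 <- assoc_cohort(rnorm(40), rep(c(TRUE, FALSE), 20))
  ch3$x2 <- ch3$x
  res3 <- fit_association(ch3, c("x", "x2"), st, risk_unit = "raw")
  expect_true("rank_deficient" %in% res3$flags)
  # empty stratum errors
  expect_error(fit_association(ch, "x", stratum_spec("Asian", "invasive",
                                                     "all"),
                               risk_unit = "raw"), "case")
})

test_that("AUC matches the pairwise oracle, handles ties, and is rank-invariant", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))$auc, 1)
  expect_equal(compute_auc(c(0.5, 0.5), c(1, 0))$auc, 0.5)
  set.seed(31)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    scores <- round(rnorm(n), 1)  # coarse scores force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    got <- compute_auc(scores, labels)
    expect_equal(got$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
    # monotone transform leaves the AUC unchanged
    expect_equal(compute_auc(exp(2 * scores), labels)$auc, got$auc,
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(1:5, rep(1, 5)), "classes")
})

test_that("risk-unit scaling rescales the OR as declared", {
  set.seed(32)
  risk <- runif(400, 0.001, 0.05)
  is_case <- rbinom(400, 1, plogis(-1 + 40 * risk)) == 1
  ch <- assoc_cohort(risk, is_case)
  ch$prs_ar5 <- risk
  st <- stratum_spec("European", "invasive", "all")
  raw <- fit_association(ch, "prs_ar5", st, risk_unit = "raw")
  pct <- fit_association(ch, "prs_ar5", st, risk_unit = "pct-point")
  expect_equal(log(unname(pct$or)) * 100, log(unname(raw$or)),
               tolerance = 1e-8)
  sd_ <- sd(risk)
  persd <- fit_association(ch, "prs_ar5", st, risk_unit = "per-sd")
  expect_equal(log(unname(persd$or)) / sd_, log(unname(raw$or)),
               tolerance = 1e-8)
})

test_that("the age-interaction Wald test flags inestimable designs", {
  ch <- assoc_cohort(rnorm(60), rep(c(TRUE, FALSE), 30))
  ch$age <- 50  # constant age
  st <- stratum_spec("European", "invasive", "all")
  expect_equal(interaction_test(ch, "x", st)$flags, "constant_age")
  ch$age <- sample(30:80, 60, replace = TRUE)
  res <- interaction_test(ch, "x", st)
  expect_true(res$p_interaction >= 0 && res$p_interaction <= 1)
})

test_that("driver analysis enumerates all 31 factor subsets", {
  ch <- generate_cohort(generator_config(n_scale = 0.004), seed = 17)
  st <- stratum_spec("European", "invasive", "all")
  tab <- driver_analysis(ch, stratum = st)
  expect_equal(nrow(tab), 31)
  expect_equal(sum(tab$full_model), 1)
  expect_equal(tab$n_factors[tab$full_model], 5)
  # full subset reproduces the standard baseline-policy Gail AUC
  scored <- score_gail(ch)
  dat <- subset_stratum(scored, st)
  ref <- compute_auc(dat$gail_ar5, as.integer(dat$status == "invasive"))
  expect_equal(tab$auc[tab$full_model], ref$auc, tolerance = 1e-12)
  # factor subsets that are 100% missing in the stratum carry no covariate
  # information: their risks collapse to the all-baseline, age-only risk, so
  # any such subsets discriminate identically and only weakly
  asian <- stratum_spec("Asian", "invasive", "all")
  tab_a <- driver_analysis(ch, stratum = asian)
  expect_equal(tab_a$auc[tab_a$factors == "n_biopsies"],
               tab_a$auc[tab_a$factors == "atypical_hyperplasia"],
               tolerance = 1e-12)
  expect_lt(abs(tab_a$auc[tab_a$factors == "n_biopsies"] - 0.5), 0.06)
})

test_that("missingness sensitivity reports both policies and reacts to case-enriched missingness", {
  # no missingness: the two policies coincide
  rows <- lapply(1:80, function(i) {
    toy_subject(sprintf("S%03d", i),
                status = if (i %% 2) "invasive" else "control",
                n_relatives = sample(c("0", "1"), 1),
                age = sample(35:75, 1))
  })
  ch <- toy_cohort(rows)
  st <- list(stratum_spec("European", "invasive", "all"))
  tab <- sensitivity_missingness(ch, strata = st)
  expect_equal(tab$auc_baseline, tab$auc_highest, tolerance = 1e-12)
  # unknowns concentrated in cases push the highest-risk policy AUC up
  ch_mnar <- generate_cohort(generator_config(n_scale = 0.008,
                                              mnar_case = 0.4), seed = 23)
  tab2 <- sensitivity_missingness(ch_mnar, strata = st)
  expect_gt(tab2$auc_highest, tab2$auc_baseline)
})
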