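mk_weights <- function(ids, weights, ea = "A", oa = "G") {
  structure(data.frame(id = ids, effect_allele = ea, other_allele = oa,
                       weight = weights, stringsAsFactors = FALSE),
            class = c("prs_weights", "data.frame"))
}

test_that("raw scoring is the weighted dosage sum with mean imputation", {
  d <- matrix(c(0, 1, 2), nrow = 3, dimnames = list(paste0("v", 1:3), "S1"))
  w <- mk_weights(paste0("v", 1:3), c(0.1, -0.2, 0.3))
  expect_equal(as.numeric(score_prs(d, w)), 0 * 0.1 + 1 * -0.2 + 2 * 0.3)

  # one missing entry imputed with the variant's mean observed dosage
  d2 <- matrix(c(NA, 0, 1, 1, 2), nrow = 1,
               dimnames = list("v1", paste0("S", 1:5)))
  got <- score_prs(d2, mk_weights("v1", 1))
  expect_equal(unname(got[1]), 1.0)  # mean of {0,1,1,2}
  # all-zero weights annihilate
  expect_equal(as.numeric(score_prs(d2, mk_weights("v1", 0))), rep(0, 5))
})

test_that("scoring matches a brute-force per-subject loop on noisy panels", {
  set.seed(21)
  m <- 30; n <- 25
  d <- matrix(rbinom(m * n, 2, 0.3), m, n,
              dimnames = list(sprintf("v%02d", 1:m), sprintf("S%02d", 1:n)))
  d[sample(length(d), 40)] <- NA
  w <- mk_weights(c(sprintf("v%02d", 1:m), "vABSENT"), rnorm(m + 1))
  got <- score_prs(d, w)
  expect_equal(as.numeric(got), loop_score_prs(d, w), tolerance = 1e-12)
  expect_equal(attr(got, "n_skipped"), 1)
})

test_that("swapped alleles are flipped and real mismatches rejected", {
  d <- matrix(c(0, 2), nrow = 2,
              dimnames = list(c("v1", "v2"), "S1"))
  w <- mk_weights(c("v1", "v2"), c(1, 1), ea = "A", oa = "G")
  al <- data.frame(id = c("v1", "v2"), effect_allele = c("A", "G"),
                   other_allele = c("G", "A"))
  # v2 dosage counts G; the weight's effect allele is A -> flip 2 -> 0
  got <- score_prs(d, w, dosage_alleles = al)
  expect_equal(as.numeric(got), 0 + 0)
  expect_equal(attr(got, "n_flipped"), 1)
  al$effect_allele[2] <- "T"
  expect_error(score_prs(d, w, dosage_alleles = al), "mismatch")
  # ambiguous A/T variants are counted and droppable
  wa <- mk_weights(c("v1", "v2"), c(1, 1), ea = "A", oa = "T")
  expect_equal(attr(score_prs(d, wa), "n_ambiguous"), 2)
  expect_equal(attr(score_prs(d, wa, ambiguous = "drop"), "n_used"), 0)
})

test_that("standardization is control-based and percentile the normal CDF", {
  p <- prs_params(mu_ctrl = 2, sd_ctrl = 0.5)
  expect_equal(standardize_prs(2, p)$z, 0)
  expect_equal(standardize_prs(2, p)$pct, 0.5)
  expect_equal(standardize_prs(2.5, p)$pct, pnorm(1))
  set.seed(4)
  raw <- rnorm(2000, 3, 2)
  is_ctrl <- rep(c(TRUE, FALSE), 1000)
  est <- estimate_prs_params(raw, is_ctrl)
  z <- standardize_prs(raw, est)$z
  expect_equal(mean(z[is_ctrl]), 0, tolerance = 1e-12)
  expect_equal(sd(z[is_ctrl]), 1, tolerance = 1e-12)
  expect_error(prs_params(sd_ctrl = 0), "sd_ctrl")
})

test_that("the theoretical OR against the middle quintile matches quadrature", {
  for (beta in c(0, 0.25, log(1.6), 1)) {
    p <- prs_params(beta = beta)
    c_num <- integrate(function(u) exp(beta * u) * dnorm(u),
                       qnorm(0.4), qnorm(0.6), rel.tol = 1e-13)$value / 0.2
    for (z in c(-2, 0, 1.5)) {
      expect_equal(rr_vs_middle_quintile(z, p), exp(beta * z) / c_num,
                   tolerance = 1e-10)
    }
  }
  # degenerate effect and monotonicity
  expect_equal(rr_vs_middle_quintile(c(-3, 0, 3), prs_params(beta = 0)),
               rep(1, 3))
  rr <- rr_vs_middle_quintile(seq(-3, 3, 0.5), prs_params(beta = 0.4))
  expect_true(all(diff(rr) > 0))
})

test_that("the population-mean baseline conserves average incidence", {
  p <- prs_params(beta = log(1.6))
  # E[rr(Z)] matches a Monte-Carlo average
  set.seed(9)
  z <- rnorm(2e5)
  expect_equal(mean(rr_vs_middle_quintile(z, p)), prs_mean_rr(p),
               tolerance = 0.01)
  # mean absolute risk over the population equals the unconstrained rr=1 risk
  rt <- flat_rates(0.004, 0.002)
  ar <- prs_five_year_risk(z, 55, p, rt)$ar5
  ref <- project_absolute_risk(rt, 55, 1, 5, use_AR_adjustment = FALSE)
  expect_equal(mean(ar), ref, tolerance = 0.01)
  # beta = 0 removes stratification entirely
  ar0 <- prs_five_year_risk(c(-2, 0, 2), 55, prs_params(beta = 0), rt)$ar5
  expect_equal(ar0, rep(ref, 3), tolerance = 1e-12)
  # mid-quintile baseline pins the central band at the population incidence
  armid <- prs_five_year_risk(0, 55, p, rt, baseline = "mid-quintile")$ar5
  expect_equal(armid, project_absolute_risk(
    rt, 55, rr_vs_middle_quintile(0, p), 5, use_AR_adjustment = FALSE),
    tolerance = 1e-12)
})

test_that("cohort PRS scoring standardizes within ancestry against controls", {
  ch <- generate_cohort(generator_config(n_scale = 0.01), seed = 13)
  scored <- score_prs_cohort(ch)
  for (anc in c("European", "Asian")) {
    zc <- scored$prs_z[scored$ancestry == anc & scored$status == "control"]
    expect_equal(mean(zc), 0, tolerance = 1e-10)
    expect_equal(sd(zc), 1, tolerance = 1e-10)
  }
  expect_true(all(scored$prs_pct > 0 & scored$prs_pct < 1))
  expect_true(all(scored$prs_ar5 > 0 & scored$prs_ar5 < 1))
})

test_that("VCF dosage reading round-trips a hand-written DS field", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tG\tA\t.\t.\t.\tDS\t0.5\t2",
    "1\t200\trs2\tC\tT\t.\t.\t.\tDS\t1\t0"), path)
  got <- read_dosages_vcf(path)
  expect_equal(got$dosages["rs1", ], c(S1 = 0.5, S2 = 2))
  expect_equal(got$alleles$effect_allele, c("A", "T"))
  w <- mk_weights(c("rs1", "rs2"), c(1, 2), ea = c("A", "T"),
                  oa = c("G", "C"))
  expect_equal(as.numeric(score_prs(got$dosages, w, got$alleles)),
               c(0.5 + 2, 2 + 0))
})
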