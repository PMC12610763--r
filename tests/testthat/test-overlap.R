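test_that("high-risk flags are boundary-inclusive and FH unknown is not flagged", {
  expect_equal(flag_high_risk(c(0.004, 0.005, 0.006), 0.005),
               c(FALSE, TRUE, TRUE))
  expect_true(all(flag_high_risk(runif(20), 0)))
  ch <- toy_cohort(list(toy_subject("A", n_relatives = "unknown"),
                        toy_subject("B", n_relatives = "1"),
                        toy_subject("C", n_relatives = "ge2"),
                        toy_subject("D", n_relatives = "0")))
  expect_equal(flag_family_history(ch), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("Venn segments count every membership pattern and sum to n", {
  p <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  g <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  f <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  seg <- venn_segments(p, g, f)
  expect_equal(unname(seg[c("PRS_only", "Gail_only", "FH_only", "PRS_Gail",
                            "PRS_Gail_FH", "none")]), c(1, 1, 0, 1, 1, 1))
  expect_equal(sum(seg), 5)
  # all-false and identical flags
  expect_equal(unname(venn_segments(!p & p, !p & p, !p & p)["none"]), 5)
  seg2 <- venn_segments(p, p, p)
  expect_equal(unname(seg2["PRS_Gail_FH"]), 3)
  expect_equal(sum(seg2[c("PRS_only", "Gail_only", "FH_only", "PRS_Gail",
                          "PRS_FH", "Gail_FH")]), 0)
  expect_error(venn_segments(p, g[1:3], f), "length")
  # property: counts sum to n for random flag triples
  set.seed(41)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    expect_equal(sum(venn_segments(runif(n) < 0.4, runif(n) < 0.4,
                                   runif(n) < 0.2)), n)
  }
})

test_that("enrichment ratios follow the definition and the minimal-threshold search is exact", {
  ch <- toy_cohort(lapply(1:200, function(i) {
    toy_subject(sprintf("S%03d", i),
                status = if (i <= 100) "invasive" else "control")
  }))
  risks <- c(rep(0.02, 20), rep(0.001, 80),   # 20/100 cases flagged at 1%
             rep(0.02, 10), rep(0.001, 90))   # 10/100 controls flagged
  st <- stratum_spec("European", "invasive", "all")
  enr <- enrichment_curve(ch, risks, st, grid = 0.01, target = 2)
  expect_equal(enr$curve$enrichment, 2)
  expect_equal(enr$min_threshold, 0.01)

  # toy vectors: minimal threshold must match an exhaustive scan
  set.seed(43)
  ch6 <- toy_cohort(lapply(1:12, function(i) {
    toy_subject(sprintf("T%02d", i),
                status = if (i <= 6) "invasive" else "control")
  }))
  r6 <- c(0.024, 0.013, 0.011, 0.009, 0.021, 0.017,
          0.006, 0.008, 0.012, 0.005, 0.010, 0.007)
  grid <- threshold_grid()
  enr6 <- enrichment_curve(ch6, r6, st, grid, target = 2)
  brute <- NA_real_
  for (t in grid) {
    e <- (sum(r6[1:6] >= t) / 6) / (sum(r6[7:12] >= t) / 6)
    if ((is.finite(e) && e >= 2) || (is.infinite(e) && sum(r6[1:6] >= t) > 0)) {
      brute <- t
      break
    }
  }
  expect_equal(enr6$min_threshold, brute)
  # zero controls flagged reports +Inf with counts kept
  top <- enr6$curve[enr6$curve$threshold == 0.022, ]
  expect_true(is.infinite(top$enrichment))
  expect_equal(top$n_controls_flagged, 0)
  expect_gt(top$n_cases_flagged, 0)
})

test_that("enrichment is about 1 under identical case/control risk distributions", {
  set.seed(44)
  n <- 4000
  ch <- toy_cohort(lapply(seq_len(2 * n), function(i) {
    toy_subject(sprintf("N%05d", i),
                status = if (i <= n) "invasive" else "control")
  }))
  risks <- rep(runif(n, 0, 0.03), 2)  # exactly equal distributions
  st <- stratum_spec("European", "invasive", "all")
  enr <- enrichment_curve(ch, risks, st)
  expect_true(all(abs(enr$curve$enrichment - 1) < 1e-12))
})

test_that("flag counts are monotone in the threshold and segments sum to stratum size", {
  ch <- generate_cohort(generator_config(n_scale = 0.005), seed = 47)
  ch <- score_gail(ch)
  ch <- score_prs_cohort(ch)
  st <- stratum_spec("European", "invasive", "all")
  enr <- enrichment_curve(ch, ch$prs_ar5, st)
  expect_true(all(diff(enr$curve$n_cases_flagged) <= 0))
  expect_true(all(diff(enr$curve$n_controls_flagged) <= 0))
  dat <- subset_stratum(ch, st)
  ff <- flag_family_history(dat)
  for (t in c(0.005, 0.015, 0.025)) {
    seg <- venn_segments(flag_high_risk(dat$prs_ar5, t),
                         flag_high_risk(dat$gail_ar5, t), ff)
    expect_equal(sum(seg), nrow(dat))
  }
})

test_that("unique-proportion curves agree with Venn segments and vanish for identical risks", {
  ch <- generate_cohort(generator_config(n_scale = 0.005), seed = 53)
  ch <- score_gail(ch)
  ch <- score_prs_cohort(ch)
  st <- stratum_spec("European", "invasive", "all")
  grid <- c(0.008, 0.02)
  uniq <- unique_proportion_curves(ch, ch$prs_ar5, ch$gail_ar5, st, grid)
  dat <- subset_stratum(ch, st)
  ff <- flag_family_history(dat)
  for (t in grid) {
    for (grp in unique(dat$status)) {
      g <- dat$status == grp
      seg <- venn_segments(flag_high_risk(dat$prs_ar5[g], t),
                           flag_high_risk(dat$gail_ar5[g], t), ff[g])
      got <- uniq[uniq$threshold == t & uniq$subgroup == grp, ]
      expect_equal(got$fraction[got$method == "PRS"],
                   unname(seg["PRS_only"]) / sum(g))
      expect_equal(got$fraction[got$method == "Gail"],
                   unname(seg["Gail_only"]) / sum(g))
      expect_equal(got$fraction[got$method == "FH"],
                   unname(seg["FH_only"]) / sum(g))
    }
  }
  # identical risk vectors can never be uniquely flagged
  uniq2 <- unique_proportion_curves(ch, ch$prs_ar5, ch$prs_ar5, st, grid)
  expect_true(all(uniq2$fraction[uniq2$method %in% c("PRS", "Gail")] == 0))
  # thresholds above every risk: model flags vanish, FH-only equals FH prevalence
  tmax <- max(ch$prs_ar5, ch$gail_ar5) + 0.001
  uniq3 <- unique_proportion_curves(ch, ch$prs_ar5, ch$gail_ar5, st,
                                    min(tmax, 0.9))
  expect_true(all(uniq3$fraction[uniq3$method %in% c("PRS", "Gail")] == 0))
  ctrl <- dat$status == "control"
  expect_equal(uniq3$fraction[uniq3$method == "FH" &
                                uniq3$subgroup == "control"],
               mean(ff[ctrl]))
})
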