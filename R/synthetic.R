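#' Generator configuration for synthetic case-control cohorts
#'
#' Loads the packaged default cell definitions (per ancestry x status cell:
#' sample size, age median/quartiles, raw-PRS location/scale, covariate
#' category counts including the unknown level) and applies any overrides.
#' Cell-level category counts are normalized to probabilities at generation
#' time, so the packaged counts double as the bookkeeping fixture for the
#' emulated consortium structure.
#'
#' @param cells optional list overriding the packaged cell definitions
#'   (same nesting: `cells$European$control$n`, ...).
#' @param n_scale multiply every cell size by this factor (rounded), for
#'   scaled-down runs.
#' @param prs_beta log OR per SD of PRS driving the case-control shift of the
#'   standardized score; a single value or a named vector with elements
#'   `invasive` and `DCIS`. Default transcribes the per-SD OR of 1.61 of the
#'   313-variant PRS.
#' @param fh_or optional odds ratio linking family history to case status;
#'   when supplied, case cells' family-history probabilities are derived from
#'   the ancestry's control cell by conditional reweighting instead of taken
#'   from the cell table.
#' @param mcar extra probability of recoding a known Gail covariate to
#'   unknown, applied to everyone (missingness is otherwise implied by the
#'   cells' unknown-category counts).
#' @param mnar_case additional unknown-recoding probability applied to cases
#'   only (exercises the direction of the missingness sensitivity analysis).
#' @param control_population_fraction fraction of controls labelled as
#'   population-based.
#' @return A `generator_config` list.
#' @export
generator_config <- function(cells = NULL, n_scale = 1,
                             prs_beta = log(1.61), fh_or = NULL,
                             mcar = 0, mnar_case = 0,
                             control_population_fraction = 0.75) {
  defaults <- jsonlite::read_json(
    system.file("extdata", "cohort_defaults_table1.json",
                package = "riskoverlap", mustWork = TRUE),
    simplifyVector = TRUE)
  cfg_cells <- defaults$cells
  if (!is.null(cells)) cfg_cells <- modifyList(cfg_cells, cells)
  if (length(prs_beta) == 1 && is.null(names(prs_beta))) {
    prs_beta <- c(invasive = unname(prs_beta), DCIS = unname(prs_beta))
  }
  stopifnot(all(c("invasive", "DCIS") %in% names(prs_beta)),
            mcar >= 0, mcar <= 1, mnar_case >= 0, mnar_case <= 1,
            control_population_fraction >= 0,
            control_population_fraction <= 1)
  for (anc in names(cfg_cells)) {
    for (st in names(cfg_cells[[anc]])) {
      cell <- cfg_cells[[anc]][[st]]
      cell$n <- as.integer(round(cell$n * n_scale))
      if (cell$n < 0) stop("cell sizes must be non-negative")
      for (v in names(.cohort_levels)[-(1:3)]) {
        cnt <- unlist(cell[[v]])
        if (any(cnt < 0) || sum(cnt) <= 0) {
          stop("invalid category counts for ", v, " in ", anc, "/", st)
        }
      }
      cfg_cells[[anc]][[st]] <- cell
    }
  }
  structure(list(cells = cfg_cells, prs_beta = prs_beta, fh_or = fh_or,
                 mcar = mcar, mnar_case = mnar_case,
                 control_population_fraction = control_population_fraction,
                 version = defaults$version),
            class = "generator_config")
}

.iqr_sd <- function(q) (q$q3 - q$q1) / (2 * qnorm(0.75))

.sample_levels <- function(n, counts) {
  p <- unlist(counts) / sum(unlist(counts))
  sample(names(p), n, replace = TRUE, prob = p)
}

# odds-tilt the family-history categories of a control cell towards cases
.tilt_fh <- function(counts, or) {
  p <- unlist(counts) / sum(unlist(counts))
  w <- ifelse(names(p) %in% c("1", "ge2"), or, 1)
  as.list(p * w / sum(p * w))
}

#' Generate a synthetic case-control cohort
#'
#' Draws a cohort with the statistical structure the analysis assumes:
#' per-cell sample sizes, truncated-normal integer ages matched to the cell
#' medians and interquartile ranges, covariate categories (including
#' unknowns) drawn from the cell probabilities, and a raw PRS that is normal
#' within each cell - standardized scale `N(0, 1)` for controls and
#' `N(delta, 1)` for cases with `delta = prs_beta` (the logit-liability
#' approximation), mapped to sum-score units through the ancestry's control
#' location and scale. Output is deterministic given the seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return A `cohort`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  pieces <- list()
  counter <- 0L
  for (anc in names(config$cells)) {
    ctrl_cell <- config$cells[[anc]][["control"]]
    mu_ctrl <- ctrl_cell$prs_raw$median
    sd_ctrl <- .iqr_sd(ctrl_cell$prs_raw)
    for (st in names(config$cells[[anc]])) {
      cell <- config$cells[[anc]][[st]]
      n <- cell$n
      if (n == 0) next
      age <- pmin(pmax(round(rnorm(n, cell$age$median, .iqr_sd(cell$age))),
                       30), 80)
      delta <- if (st == "control") 0 else unname(config$prs_beta[[st]])
      z <- rnorm(n, delta, 1)
      fh_counts <- cell$n_relatives
      if (!is.null(config$fh_or) && st != "control") {
        fh_counts <- .tilt_fh(ctrl_cell$n_relatives, config$fh_or)
      }
      df <- data.frame(
        subject_id = sprintf("S%07d", counter + seq_len(n)),
        study_id = paste0(substr(anc, 1, 3), "_STUDY"),
        ancestry = anc, age = age, status = st,
        control_source = if (st == "control") {
          ifelse(runif(n) < config$control_population_fraction,
                 "population", "other")
        } else "not_applicable",
        age_menarche = .sample_levels(n, cell$age_menarche),
        age_first_birth = .sample_levels(n, cell$age_first_birth),
        n_relatives = .sample_levels(n, fh_counts),
        n_biopsies = .sample_levels(n, cell$n_biopsies),
        atypical_hyperplasia = .sample_levels(n, cell$atypical_hyperplasia),
        prs_raw = mu_ctrl + z * sd_ctrl,
        stringsAsFactors = FALSE)
      counter <- counter + n
      pieces[[length(pieces) + 1]] <- df
    }
  }
  subjects <- do.call(rbind, pieces)
  # extra missingness, applied last: MCAR for everyone, MNAR for cases
  p_unk <- config$mcar +
    ifelse(subjects$status == "control", 0, config$mnar_case)
  if (any(p_unk > 0)) {
    for (v in .gail_recoded) {
      hit <- runif(nrow(subjects)) < p_unk
      subjects[[v]][hit] <- "unknown"
    }
  }
  cohort <- new_cohort(subjects)
  .log_step(cohort, sprintf(
    "generate_cohort: %d subjects, seed %d, prs_beta inv=%.3f dcis=%.3f",
    nrow(subjects), seed, config$prs_beta[["invasive"]],
    config$prs_beta[["DCIS"]]))
}

#' Generate a dosage panel consistent with a cohort's raw PRS
#'
#' Samples `m` Hardy-Weinberg variants (genotype dosages 0/1/2 at the stated
#' effect-allele frequencies) with normal weights, then adds two synthetic
#' adjustment variants (`ADJ_POS`, `ADJ_NEG`, continuous dosages in
#' `[0, 2]`) whose weighted contribution absorbs each subject's residual, so
#' that the weighted sum reproduces the cohort's assigned raw PRS to within
#' `tolerance`. A missing mask can be applied to the Hardy-Weinberg variants
#' for imputation tests (reconstruction is exact only at zero missingness).
#'
#' @param cohort a `cohort` with `prs_raw`.
#' @param m number of Hardy-Weinberg variants.
#' @param maf_range effect-allele frequency range to draw from.
#' @param weight_sd SD of the normal variant weights.
#' @param missing_rate per-entry missingness probability on the
#'   Hardy-Weinberg variants.
#' @param seed integer seed.
#' @param tolerance maximum per-subject reconstruction residual.
#' @return list with `dosages` (matrix, variants x subjects), `weights`
#'   (data frame `id`, `effect_allele`, `other_allele`, `weight`), `freqs`.
#' @export
generate_dosages <- function(cohort, m = 50, maf_range = c(0.05, 0.5),
                             weight_sd = 0.05, missing_rate = 0,
                             seed = 1L, tolerance = 1e-8) {
  set.seed(seed)
  n <- nrow(cohort)
  freqs <- runif(m, maf_range[1], maf_range[2])
  w <- rnorm(m, 0, weight_sd)
  geno <- vapply(freqs, function(f) rbinom(n, 2L, f), numeric(n))
  d <- t(geno)  # variants x subjects
  ids <- sprintf("rs%06d", seq_len(m))
  rownames(d) <- ids
  colnames(d) <- cohort$subject_id
  resid <- cohort$prs_raw - as.numeric(crossprod(d, w))
  w_adj <- max(max(abs(resid)) / 2, 1e-6)
  d_pos <- ifelse(resid > 0, resid / w_adj, 0)
  d_neg <- ifelse(resid < 0, -resid / w_adj, 0)
  if (any(d_pos > 2 + 1e-12) || any(d_neg > 2 + 1e-12)) {
    stop("residual adjustment infeasible at the requested tolerance")
  }
  dosages <- rbind(d, ADJ_POS = d_pos, ADJ_NEG = d_neg)
  weights <- data.frame(
    id = c(ids, "ADJ_POS", "ADJ_NEG"),
    effect_allele = c(sample(c("A", "G"), m, replace = TRUE), "A", "A"),
    other_allele = "C",
    weight = c(w, w_adj, -w_adj), stringsAsFactors = FALSE)
  weights$other_allele[weights$effect_allele == "C"] <- "T"
  check <- as.numeric(crossprod(dosages, weights$weight))
  if (max(abs(check - cohort$prs_raw)) > tolerance) {
    stop("dosage panel failed to reproduce raw scores within tolerance")
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(m * n) < missing_rate, m, n)
    dosages[seq_len(m), ][mask] <- NA_real_
  }
  list(dosages = dosages,
       weights = structure(weights,
                           class = c("prs_weights", "data.frame")),
       freqs = freqs)
}

#' Generate outcomes with optionally miscalibrated predicted risks
#'
#' True risks are drawn on the logit scale, outcomes as Bernoulli(true
#' risk); predicted risks equal the truth under `"none"`, are multiplied by
#' `factor` under `"scale"`, or shifted by `shift` logits under `"shift"`,
#' clipped to (0, 1). Exercises the power of the calibration tests.
#'
#' @param n subjects.
#' @param distortion `"none"`, `"scale"` or `"shift"`.
#' @param factor multiplicative distortion of the risk scale.
#' @param shift additive logit shift.
#' @param mean_logit,sd_logit location/scale of the true-risk logits.
#' @param seed integer seed.
#' @return list with `true_risk`, `predicted`, `outcome`.
#' @export
generate_miscalibrated <- function(n, distortion = c("none", "scale",
                                                     "shift"),
                                   factor = 0.5, shift = 0,
                                   mean_logit = qlogis(0.1), sd_logit = 1,
                                   seed = 1L) {
  distortion <- match.arg(distortion)
  set.seed(seed)
  truth <- plogis(rnorm(n, mean_logit, sd_logit))
  predicted <- switch(distortion,
                      none = truth,
                      scale = truth * factor,
                      shift = plogis(qlogis(truth) + shift))
  eps <- 1e-12
  predicted <- pmin(pmax(predicted, eps), 1 - eps)
  list(true_risk = truth, predicted = predicted,
       outcome = rbinom(n, 1L, truth))
}
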