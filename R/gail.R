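#' Gail model 2 coefficient table
#'
#' Loads the packaged, versioned log relative-risk coefficient table of the
#' parsimonious Gail model (five covariates: age at menarche, age at first
#' live birth, number of breast biopsies with an age-regime interaction,
#' first-degree family history with a first-birth interaction, and an
#' atypical-hyperplasia multiplier applied only when at least one biopsy was
#' taken). The model itself never appears in the consortium data files, so
#' the constants live in `inst/extdata` with provenance notes and any
#' user-supplied table of the same shape is accepted.
#'
#' @param path optional path to an alternative JSON coefficient table.
#' @return A `gail_coefficients` list.
#' @export
gail_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gail_model2_coefficients.json",
                        package = "riskoverlap", mustWork = TRUE)
  }
  cf <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(cf$log_rr) != cf$checksum_terms) {
    stop("coefficient table failed its term-count checksum")
  }
  structure(cf, class = "gail_coefficients")
}

#' Highest-relative-risk category of a Gail covariate
#'
#' Argmax of the packaged main-effect log relative risks over a covariate's
#' levels, ties resolved to the later-listed category. Used to define the
#' `highest_risk` missing-data policy mapping.
#'
#' @param coeffs a [gail_coefficients()].
#' @param covariate one of the four recoded Gail covariates.
#' @export
gail_highest_risk_level <- function(coeffs, covariate) {
  codes <- coeffs$category_code[[covariate]]
  lrr <- coeffs$log_rr[[covariate]] * unlist(codes)
  names(codes)[max(which(lrr == max(lrr)))]
}

.gail_code <- function(coeffs, covariate, values) {
  codes <- coeffs$category_code[[covariate]]
  if (any(!values %in% names(codes))) {
    stop(sprintf("unknown level reached the Gail engine for '%s'; apply a missing policy first",
                 covariate))
  }
  unlist(codes)[values]
}

#' Gail relative risk
#'
#' Computes `rr = exp(sum of selected log-coefficients) * hyperplasia
#' multiplier` for each subject of a policy-applied cohort. The biopsy term
#' uses the age-regime (< 50 vs >= 50 years) coefficient; with zero biopsies
#' the hyperplasia multiplier is 1 regardless of the recorded flag. All
#' covariates at reference give rr = 1.
#'
#' @param cohort a `cohort` (or data frame slice) with no `"unknown"` left in
#'   the four recoded Gail covariates.
#' @param coeffs a [gail_coefficients()].
#' @return Numeric vector of relative risks (> 0).
#' @export
gail_relative_risk <- function(cohort, coeffs = gail_coefficients()) {
  am <- .gail_code(coeffs, "age_menarche", cohort$age_menarche)
  af <- .gail_code(coeffs, "age_first_birth", cohort$age_first_birth)
  nr <- .gail_code(coeffs, "n_relatives", cohort$n_relatives)
  nb <- .gail_code(coeffs, "n_biopsies", cohort$n_biopsies)
  b <- coeffs$log_rr
  ge50 <- as.numeric(cohort$age >= 50)
  lp <- b$age_menarche * am +
    (b$n_biopsies + b$biopsies_x_age_ge50 * ge50) * nb +
    b$age_first_birth * af +
    b$n_relatives * nr +
    b$first_birth_x_relatives * af * nr
  mult <- ifelse(nb == 0, 1,
                 unlist(coeffs$hyperplasia_multiplier)[
                   cohort$atypical_hyperplasia])
  unname(exp(lp) * mult)
}

#' Gail five-year absolute risk
#'
#' Projects each subject's Gail relative risk to an absolute risk over the
#' next `horizon` years using the ancestry-mapped rate table, with the
#' attributable-risk adjustment applied (composite incidence times
#' `one_minus_AR` is the baseline hazard the relative risk multiplies).
#'
#' @param cohort policy-applied `cohort`.
#' @param coeffs a [gail_coefficients()].
#' @param rates named list of [rate_table()]s keyed by ancestry (default
#'   European -> packaged White table, Asian -> packaged Chinese table).
#' @param horizon years (default 5).
#' @return data frame with columns `rr` and `ar5`, one row per subject.
#' @export
gail_five_year_risk <- function(cohort, coeffs = gail_coefficients(),
                                rates = default_rates_map(), horizon = 5) {
  rr <- gail_relative_risk(cohort, coeffs)
  ar5 <- rep(NA_real_, nrow(cohort))
  for (anc in unique(cohort$ancestry)) {
    if (is.null(rates[[anc]])) stop("no rate table mapped for ancestry ", anc)
    idx <- cohort$ancestry == anc
    ar5[idx] <- project_absolute_risk(rates[[anc]], cohort$age[idx], rr[idx],
                                      horizon, use_AR_adjustment = TRUE)
  }
  data.frame(rr = rr, ar5 = ar5)
}

#' Default ancestry to rate-table mapping
#'
#' European ancestry projects against the "White" table and Asian ancestry
#' against the "Chinese" table; override per run by supplying any named list
#' of rate tables.
#' @export
default_rates_map <- function() {
  list(European = default_rate_table("White"),
       Asian = default_rate_table("Chinese"))
}

#' Score a cohort with the Gail engine
#'
#' Applies the missing-data policy, computes relative and five-year absolute
#' risk, and appends `gail_rr` and `gail_ar5` columns to the cohort.
#'
#' @inheritParams gail_five_year_risk
#' @param policy a [missing_policy()] (default baseline recode).
#' @return The input `cohort` with `gail_rr`, `gail_ar5` appended.
#' @export
score_gail <- function(cohort, coeffs = gail_coefficients(),
                       rates = default_rates_map(),
                       policy = missing_policy("baseline"), horizon = 5) {
  recoded <- apply_missing_policy(cohort, policy)
  res <- gail_five_year_risk(recoded, coeffs, rates, horizon)
  cohort$gail_rr <- res$rr
  cohort$gail_ar5 <- res$ar5
  .log_step(cohort, sprintf("score_gail: %s policy, %d subjects scored",
                            policy$mode, nrow(cohort)))
}
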