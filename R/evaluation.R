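#' Analysis stratum specification
#'
#' Analyses are stratified by disease (invasive vs DCIS, each sharing the
#' control pool), genetic ancestry, age group (< 50 vs >= 50 years at
#' interview/diagnosis), and optionally restricted to population-based
#' controls.
#'
#' @param ancestry `"European"`, `"Asian"`, or `NULL` for both.
#' @param disease `"invasive"` or `"DCIS"`.
#' @param age_group `"all"`, `"lt50"` or `"ge50"`.
#' @param controls `"all"` or `"population_based"`.
#' @return A `stratum_spec` list.
#' @export
stratum_spec <- function(ancestry = NULL,
                         disease = c("invasive", "DCIS"),
                         age_group = c("all", "lt50", "ge50"),
                         controls = c("all", "population_based")) {
  structure(list(ancestry = ancestry, disease = match.arg(disease),
                 age_group = match.arg(age_group),
                 controls = match.arg(controls)),
            class = "stratum_spec")
}

#' Subset a cohort to a stratum
#'
#' Keeps the stratum's cases and the (possibly population-based) controls;
#' the other disease group is excluded entirely.
#'
#' @param cohort a `cohort`.
#' @param stratum a [stratum_spec()].
#' @return A `cohort` containing only the stratum's cases and controls.
#' @export
subset_stratum <- function(cohort, stratum) {
  keep <- cohort$status %in% c("control", stratum$disease)
  if (stratum$controls == "population_based") {
    keep <- keep & (cohort$status != "control" |
                      cohort$control_source == "population")
  }
  if (!is.null(stratum$ancestry)) {
    keep <- keep & cohort$ancestry %in% stratum$ancestry
  }
  keep <- keep & switch(stratum$age_group,
                        all = TRUE,
                        lt50 = cohort$age < 50,
                        ge50 = cohort$age >= 50)
  cohort[keep, , drop = FALSE]
}

#' Area under the ROC curve with DeLong interval
#'
#' Rank (Mann-Whitney) AUC estimator with ties counted one half, and a
#' DeLong-type 95% confidence interval. A constant score vector carries no
#' ranking information and returns AUC 0.5 with a degeneracy flag.
#'
#' @param scores per-subject risk scores.
#' @param labels 0/1 (or logical) outcome labels; both classes must be
#'   present.
#' @return list with `auc`, `ci` (length 2), `method`, `degenerate`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both outcome classes must be present")
  if (length(unique(scores)) < 2) {
    return(list(auc = 0.5, ci = c(NA_real_, NA_real_), method = "delong",
                degenerate = TRUE))
  }
  roc <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  list(auc = as.numeric(pROC::auc(roc)), ci = ci[c(1, 3)],
       method = "delong", degenerate = FALSE)
}

#' Logistic association between predicted risk and case status
#'
#' Maximum-likelihood logistic regression of case status on one or more
#' predictor columns (e.g., the five-year absolute risks of one model, or the
#' PRS and Gail risks jointly), scaled per `risk_unit`, within a stratum.
#' Odds ratios carry Wald 95% intervals. Perfect separation and rank
#' deficiency are flagged, never silently reported as coefficients.
#'
#' @param cohort a scored `cohort`.
#' @param predictors character vector of risk column names.
#' @param stratum a [stratum_spec()].
#' @param risk_unit `"pct-point"` (per percentage point of absolute risk,
#'   i.e. predictor x 100), `"per-sd"` (per within-stratum SD), or `"raw"`
#'   (no rescaling).
#' @return An `assoc_result` list: `or`, `or_ci` (matrix), `auc`, `auc_ci`,
#'   `n_cases`, `n_controls`, `p_values`, `flags`.
#' @export
fit_association <- function(cohort, predictors, stratum,
                            risk_unit = c("pct-point", "per-sd", "raw")) {
  risk_unit <- match.arg(risk_unit)
  dat <- subset_stratum(cohort, stratum)
  y <- as.integer(dat$status == stratum$disease)
  if (sum(y) == 0 || sum(1 - y) == 0) {
    stop("stratum must contain at least one case and one control")
  }
  X <- as.data.frame(dat)[, predictors, drop = FALSE]
  for (p in predictors) {
    X[[p]] <- switch(risk_unit,
                     "pct-point" = X[[p]] * 100,
                     "per-sd" = X[[p]] / sd(X[[p]]),
                     raw = X[[p]])
  }
  flags <- character()
  fit <- withCallingHandlers(
    glm(y ~ ., data = cbind(y = y, X), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        flags <<- union(flags, "separation")
      }
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)[-1]
  if (anyNA(cf)) flags <- union(flags, "rank_deficient")
  if (any(abs(cf) > 15, na.rm = TRUE)) flags <- union(flags, "separation")
  se <- sqrt(diag(vcov(fit)))[-1]
  or_ci <- cbind(lower = exp(cf - 1.959964 * se),
                 upper = exp(cf + 1.959964 * se))
  score <- if (length(predictors) == 1) X[[1]] else fit$linear.predictors
  auc <- compute_auc(score, y)
  structure(list(or = exp(cf), or_ci = or_ci, auc = auc$auc,
                 auc_ci = auc$ci, n_cases = sum(y),
                 n_controls = sum(1 - y),
                 p_values = 2 * pnorm(-abs(cf / se)), flags = flags),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("logistic association: %d cases / %d controls\n",
              x$n_cases, x$n_controls))
  for (i in seq_along(x$or)) {
    cat(sprintf("  OR[%s] = %.3f (%.3f-%.3f)\n", names(x$or)[i], x$or[i],
                x$or_ci[i, 1], x$or_ci[i, 2]))
  }
  cat(sprintf("  AUC = %.3f (%.3f-%.3f) [%s]\n", x$auc, x$auc_ci[1],
              x$auc_ci[2], "delong"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Age-interaction test for a risk score
#'
#' Logistic fit of status on the risk score, continuous age, and their
#' product; the reported p-value is the Wald test of the interaction
#' coefficient, assessing heterogeneity of the score effect by age.
#'
#' @param cohort scored `cohort`.
#' @param predictor risk column name.
#' @param stratum a [stratum_spec()] (typically `age_group = "all"`).
#' @return list with `p_interaction`, `estimate`, `flags`.
#' @export
interaction_test <- function(cohort, predictor, stratum) {
  dat <- subset_stratum(cohort, stratum)
  y <- as.integer(dat$status == stratum$disease)
  x <- as.data.frame(dat)[[predictor]]
  age <- dat$age
  if (length(unique(age)) < 2) {
    return(list(p_interaction = NA_real_, estimate = NA_real_,
                flags = "constant_age"))
  }
  fit <- suppressWarnings(glm(y ~ x * age, family = binomial()))
  cf <- coef(fit)["x:age"]
  if (is.na(cf)) {
    return(list(p_interaction = NA_real_, estimate = NA_real_,
                flags = "inestimable"))
  }
  se <- sqrt(vcov(fit)["x:age", "x:age"])
  list(p_interaction = unname(2 * pnorm(-abs(cf / se))),
       estimate = unname(cf), flags = character())
}

#' Driver analysis of the Gail model's discrimination
#'
#' For every non-empty subset of the five Gail factors, covariates outside
#' the subset are set to missing (hence recoded to baseline), the five-year
#' risk is recomputed, and the stratum AUC is reported: 31 rows, the
#' full-factor row flagged. A subset whose factors are entirely missing in
#' the stratum yields a constant risk and AUC 0.5 by convention.
#'
#' @param cohort a `cohort`.
#' @param coeffs a [gail_coefficients()].
#' @param rates ancestry-keyed rate-table list.
#' @param stratum a [stratum_spec()].
#' @return data frame: `factors`, `n_factors`, `auc`, `auc_lo`, `auc_hi`,
#'   `full_model`.
#' @export
driver_analysis <- function(cohort, coeffs = gail_coefficients(),
                            rates = default_rates_map(), stratum) {
  factors <- c("age_menarche", "age_first_birth", "n_relatives",
               "n_biopsies", "atypical_hyperplasia")
  dat <- subset_stratum(cohort, stratum)
  y <- as.integer(dat$status == stratum$disease)
  rows <- list()
  for (k in seq_along(factors)) {
    for (idx in utils::combn(length(factors), k, simplify = FALSE)) {
      sub <- factors[idx]
      masked <- dat
      for (v in setdiff(factors, sub)) masked[[v]] <- "unknown"
      masked <- apply_missing_policy(masked, missing_policy("baseline"))
      ar5 <- gail_five_year_risk(masked, coeffs, rates)$ar5
      auc <- compute_auc(ar5, y)
      rows[[length(rows) + 1]] <- data.frame(
        factors = paste(sub, collapse = "+"), n_factors = k,
        auc = auc$auc, auc_lo = auc$ci[1], auc_hi = auc$ci[2],
        full_model = k == length(factors))
    }
  }
  do.call(rbind, rows)
}

#' Missing-data sensitivity analysis
#'
#' Recomputes the Gail five-year risk under the baseline and highest-risk
#' missing-data policies and reports the stratum AUCs side by side. With no
#' missingness the two columns coincide.
#'
#' @param cohort a `cohort`.
#' @param coeffs a [gail_coefficients()].
#' @param rates ancestry-keyed rate-table list.
#' @param strata list of [stratum_spec()]s.
#' @return data frame, one row per stratum, with both policies' AUCs and CIs.
#' @export
sensitivity_missingness <- function(cohort, coeffs = gail_coefficients(),
                                    rates = default_rates_map(), strata) {
  rows <- lapply(strata, function(st) {
    dat <- subset_stratum(cohort, st)
    y <- as.integer(dat$status == st$disease)
    aucs <- lapply(c("baseline", "highest_risk"), function(mode) {
      rec <- apply_missing_policy(dat, missing_policy(mode))
      compute_auc(gail_five_year_risk(rec, coeffs, rates)$ar5, y)
    })
    data.frame(ancestry = paste(st$ancestry %||% "both", collapse = "+"),
               disease = st$disease, age_group = st$age_group,
               auc_baseline = aucs[[1]]$auc,
               auc_baseline_lo = aucs[[1]]$ci[1],
               auc_baseline_hi = aucs[[1]]$ci[2],
               auc_highest = aucs[[2]]$auc,
               auc_highest_lo = aucs[[2]]$ci[1],
               auc_highest_hi = aucs[[2]]$ci[2])
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
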