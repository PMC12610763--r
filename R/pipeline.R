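#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs. Inputs may be file paths (read
#' with the package readers) or in-memory objects; referenced paths must
#' exist at configuration time. The configuration is echoed verbatim into
#' the output directory so every stage is individually reproducible.
#'
#' @param phenotypes a `cohort`, or path to a phenotype table.
#' @param rates ancestry-keyed list of rate tables (default packaged map).
#' @param coeffs a [gail_coefficients()] or path to a coefficient JSON.
#' @param weights optional [read_prs_weights()] table or path.
#' @param dosages optional variant x subject dosage matrix; when absent the
#'   cohort's `prs_raw` column is used.
#' @param strata list of [stratum_spec()]s (default: ancestry x disease x
#'   age-group grid over the cohort).
#' @param grid threshold grid.
#' @param policy missing-data policy for the Gail engine.
#' @param beta log OR per SD of PRS.
#' @param enrichment_target case-enrichment multiple to search for.
#' @param n_boot calibration bootstrap resamples.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir optional output directory for the report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(phenotypes, rates = default_rates_map(),
                       coeffs = gail_coefficients(), weights = NULL,
                       dosages = NULL, strata = NULL,
                       grid = threshold_grid(),
                       policy = missing_policy("baseline"),
                       beta = log(1.61), enrichment_target = 2,
                       n_boot = 500, seed = 1L, out_dir = NULL) {
  if (is.null(phenotypes)) stop("run_config: missing field 'phenotypes'")
  if (is.null(rates)) stop("run_config: missing field 'rates'")
  for (nm in c("phenotypes", "coeffs", "weights")) {
    val <- get(nm)
    if (is.character(val) && !file.exists(val)) {
      stop(sprintf("run_config: file for '%s' does not exist: %s", nm, val))
    }
  }
  structure(list(phenotypes = phenotypes, rates = rates, coeffs = coeffs,
                 weights = weights, dosages = dosages, strata = strata,
                 grid = grid, policy = policy, beta = beta,
                 enrichment_target = enrichment_target, n_boot = n_boot,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.default_strata <- function(cohort) {
  out <- list()
  for (anc in unique(cohort$ancestry)) {
    for (dis in intersect(c("invasive", "DCIS"), unique(cohort$status))) {
      for (ag in c("all", "lt50", "ge50")) {
        out[[length(out) + 1]] <- stratum_spec(anc, dis, ag)
      }
    }
  }
  out
}

.stratum_label <- function(st) {
  sprintf("%s_%s_%s", paste(st$ancestry %||% "both", collapse = "+"),
          st$disease, st$age_group)
}

#' Run the full risk-stratification analysis
#'
#' Executes prepare (read, individual and study filters), Gail scoring, PRS
#' scoring, stratified evaluation (ORs, AUCs, age-interaction tests, joint
#' PRS+Gail fits), threshold overlap (Venn segments, unique proportions,
#' enrichment curves with minimal-threshold search), mROC calibration against
#' the European >= 50 reference, and the Gail driver analysis. Every stage
#' logs its input/output row counts; results are deterministic given the
#' configured seed. When `out_dir` is set, a JSON report, TSV tables and the
#' echoed configuration are written there.
#'
#' @param config a [run_config()].
#' @return A `pipeline_report` list with one element per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  coeffs <- if (is.character(config$coeffs)) gail_coefficients(config$coeffs)
            else config$coeffs
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  cohort <- .stage("prepare", {
    ch <- if (is.character(config$phenotypes)) {
      read_phenotypes(config$phenotypes)
    } else config$phenotypes
    n0 <- nrow(ch)
    ch <- filter_individuals(ch)
    ch <- filter_studies(ch)
    note("prepare: %d subjects in, %d retained", n0, nrow(ch))
    ch
  })

  cohort <- .stage("score-gail", {
    out <- score_gail(cohort, coeffs, config$rates, config$policy)
    note("score-gail: %d subjects scored", sum(!is.na(out$gail_ar5)))
    out
  })

  cohort <- .stage("score-prs", {
    raw <- NULL
    if (!is.null(config$dosages)) {
      weights <- if (is.character(config$weights)) {
        read_prs_weights(config$weights)
      } else config$weights
      raw <- score_prs(config$dosages, weights)
    }
    out <- score_prs_cohort(cohort, raw = raw, beta = config$beta,
                            rates = config$rates)
    note("score-prs: %d subjects scored", sum(!is.na(out$prs_ar5)))
    out
  })

  strata <- config$strata %||% .default_strata(cohort)

  evaluation <- .stage("evaluate", {
    rows <- lapply(strata, function(st) {
      res_p <- fit_association(cohort, "prs_ar5", st)
      res_g <- fit_association(cohort, "gail_ar5", st)
      joint <- fit_association(cohort, c("prs_ar5", "gail_ar5"), st)
      int_p <- if (st$age_group == "all") {
        interaction_test(cohort, "prs_ar5", st)$p_interaction
      } else NA_real_
      int_g <- if (st$age_group == "all") {
        interaction_test(cohort, "gail_ar5", st)$p_interaction
      } else NA_real_
      data.frame(stratum = .stratum_label(st),
                 n_cases = res_p$n_cases, n_controls = res_p$n_controls,
                 or_prs = unname(res_p$or), auc_prs = res_p$auc,
                 auc_prs_lo = res_p$auc_ci[1], auc_prs_hi = res_p$auc_ci[2],
                 or_gail = unname(res_g$or), auc_gail = res_g$auc,
                 auc_gail_lo = res_g$auc_ci[1],
                 auc_gail_hi = res_g$auc_ci[2],
                 auc_joint = joint$auc,
                 p_interaction_prs = int_p, p_interaction_gail = int_g)
    })
    out <- do.call(rbind, rows)
    note("evaluate: %d strata", nrow(out))
    out
  })

  overlap <- .stage("overlap", {
    res <- lapply(strata, function(st) {
      enr_p <- enrichment_curve(cohort, cohort$prs_ar5, st, config$grid,
                                config$enrichment_target)
      enr_g <- enrichment_curve(cohort, cohort$gail_ar5, st, config$grid,
                                config$enrichment_target)
      uniq <- unique_proportion_curves(cohort, cohort$prs_ar5,
                                       cohort$gail_ar5, st, config$grid)
      list(stratum = .stratum_label(st),
           min_threshold_prs = enr_p$min_threshold,
           min_threshold_gail = enr_g$min_threshold,
           enrichment_prs = enr_p$curve, enrichment_gail = enr_g$curve,
           unique_proportions = uniq)
    })
    note("overlap: %d strata x %d thresholds", length(res),
         length(config$grid))
    names(res) <- vapply(res, `[[`, "", "stratum")
    res
  })

  calibration <- .stage("calibrate", {
    ref <- stratum_spec("European", "invasive", "ge50")
    ref_dat <- subset_stratum(cohort, ref)
    reference_roc <- if (nrow(ref_dat) > 0 &&
                           length(unique(ref_dat$status)) > 1) {
      empirical_roc(ref_dat$prs_ar5,
                    as.integer(ref_dat$status == "invasive"))
    } else NULL
    res <- lapply(strata[vapply(strata, function(s) s$age_group != "all",
                                logical(1))], function(st) {
      dat <- subset_stratum(cohort, st)
      y <- as.integer(dat$status == st$disease)
      out <- lapply(c(prs = "prs_ar5", gail = "gail_ar5"), function(col) {
        calibration_tests(pmin(pmax(as.data.frame(dat)[[col]], 1e-12),
                               1 - 1e-12),
                          y, n_boot = config$n_boot, seed = config$seed)
      })
      list(stratum = .stratum_label(st),
           p_mean_prs = out$prs$p_mean,
           p_roc_equality_prs = out$prs$p_roc_equality,
           p_unified_prs = out$prs$p_unified,
           p_mean_gail = out$gail$p_mean,
           p_roc_equality_gail = out$gail$p_roc_equality,
           p_unified_gail = out$gail$p_unified,
           reference_roc = reference_roc)
    })
    note("calibrate: %d strata, %d bootstrap resamples", length(res),
         config$n_boot)
    names(res) <- vapply(res, `[[`, "", "stratum")
    res
  })

  drivers <- .stage("drivers", {
    res <- lapply(strata[vapply(strata, function(s) {
      s$disease == "invasive" && s$age_group != "all"
    }, logical(1))], function(st) {
      driver_analysis(cohort, coeffs, config$rates, st)
    })
    names(res) <- vapply(strata[vapply(strata, function(s) {
      s$disease == "invasive" && s$age_group != "all"
    }, logical(1))], .stratum_label, "")
    note("drivers: %d strata x 31 factor subsets", length(res))
    res
  })

  report <- structure(list(schema = "riskoverlap-report/1.0",
                           seed = config$seed,
                           provenance = provenance(cohort),
                           log = log_lines, cohort = cohort,
                           evaluation = evaluation, overlap = overlap,
                           calibration = calibration, drivers = drivers),
                      class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phenotypes(cohort, file.path(config$out_dir,
                                       "scored_phenotypes.tsv"))
    write.table(evaluation, file.path(config$out_dir, "evaluation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    slim <- unclass(report)
    slim$cohort <- NULL
    jsonlite::write_json(slim, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
    cfg_echo <- config
    cfg_echo$phenotypes <- if (is.character(config$phenotypes)) {
      config$phenotypes
    } else "<in-memory cohort>"
    cfg_echo$rates <- names(config$rates)
    cfg_echo$dosages <- if (is.null(config$dosages)) NULL else "<matrix>"
    jsonlite::write_json(lapply(unclass(cfg_echo), function(x) {
      if (is.data.frame(x) || inherits(x, "gail_coefficients")) "<object>"
      else unclass(x)
    }), file.path(config$out_dir, "config_echo.json"),
    auto_unbox = TRUE, na = "null", force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (schema", x$schema, ")\n")
  cat(paste(" -", x$log, collapse = "\n"), "\n")
  invisible(x)
}
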