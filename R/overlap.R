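#' Absolute-risk threshold grid
#'
#' Default grid sweeps five-year absolute-risk thresholds from 0.5% to 2.5%
#' in 0.1-percentage-point steps, the granularity at which high-risk overlap
#' is assessed.
#'
#' @param lo,hi grid bounds as risk fractions (`0 < lo < hi < 1`).
#' @param step grid step as a risk fraction.
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(lo = 0.005, hi = 0.025, step = 0.001) {
  stopifnot(lo > 0, lo < hi, hi < 1, step > 0)
  round(seq(lo, hi, by = step), 10)
}

#' Flag subjects as high-risk at an absolute-risk threshold
#'
#' Boundary-inclusive: a subject whose risk equals the threshold is flagged,
#' so a quoted threshold like 1.4% flags subjects at exactly that risk.
#'
#' @param risks per-subject five-year absolute risks in `[0, 1]`.
#' @param threshold risk fraction.
#' @return Logical vector.
#' @export
flag_high_risk <- function(risks, threshold) {
  stopifnot(all(risks >= 0 & risks <= 1, na.rm = TRUE))
  risks >= threshold
}

#' Family-history high-risk flag
#'
#' Binary and threshold-free: at least one first-degree relative with breast
#' cancer. Subjects with unknown family history are considered to have none
#' and are not flagged.
#'
#' @param cohort a `cohort`.
#' @return Logical vector.
#' @export
flag_family_history <- function(cohort) {
  cohort$n_relatives %in% c("1", "ge2")
}

#' Venn segment counts over three high-risk flags
#'
#' Counts the eight membership patterns of {PRS, Gail, FH} high-risk flags:
#' the seven non-empty Venn segments plus the unflagged remainder. Segment
#' counts always sum to the input length.
#'
#' @param flags_prs,flags_gail,flags_fh logical vectors of equal length.
#' @return Named integer vector: `PRS_only`, `Gail_only`, `FH_only`,
#'   `PRS_Gail`, `PRS_FH`, `Gail_FH`, `PRS_Gail_FH`, `none`.
#' @export
venn_segments <- function(flags_prs, flags_gail, flags_fh) {
  n <- length(flags_prs)
  if (length(flags_gail) != n || length(flags_fh) != n) {
    stop("flag vectors must have equal length")
  }
  pattern <- flags_prs + 2L * flags_gail + 4L * flags_fh
  counts <- tabulate(pattern + 1L, nbins = 8L)
  c(PRS_only = counts[2], Gail_only = counts[3], FH_only = counts[5],
    PRS_Gail = counts[4], PRS_FH = counts[6], Gail_FH = counts[7],
    PRS_Gail_FH = counts[8], none = counts[1])
}

#' Case-enrichment curve across thresholds
#'
#' At each threshold `t`, the enrichment ratio compares how readily the risk
#' model flags cases versus controls. Under the default `"flagged-fraction"`
#' definition it is
#' `(n cases flagged / n cases) / (n controls flagged / n controls)`; the
#' `"flagged-count"` alternative is the raw ratio of flagged cases to flagged
#' controls (the composition of the flagged set). The minimal threshold on
#' the grid at which enrichment reaches `target` (default 2, "twice as many
#' cases as controls") is returned alongside the curve; a threshold flagging
#' zero controls yields `Inf` with its counts retained for context.
#'
#' @param cohort a `cohort`.
#' @param risks per-subject absolute risks (same order as `cohort`).
#' @param stratum a [stratum_spec()].
#' @param grid thresholds from [threshold_grid()].
#' @param target enrichment multiple to search for.
#' @param definition `"flagged-fraction"` or `"flagged-count"`.
#' @return list with `curve` (data frame: threshold, n_cases_flagged,
#'   n_controls_flagged, enrichment) and `min_threshold` (NA if the target is
#'   never reached on the grid).
#' @export
enrichment_curve <- function(cohort, risks, stratum,
                             grid = threshold_grid(), target = 2,
                             definition = c("flagged-fraction",
                                            "flagged-count")) {
  definition <- match.arg(definition)
  keep <- cohort$status %in% c("control", stratum$disease)
  if (stratum$controls == "population_based") {
    keep <- keep & (cohort$status != "control" |
                      cohort$control_source == "population")
  }
  if (!is.null(stratum$ancestry)) {
    keep <- keep & cohort$ancestry %in% stratum$ancestry
  }
  keep <- keep & switch(stratum$age_group, all = TRUE,
                        lt50 = cohort$age < 50, ge50 = cohort$age >= 50)
  is_case <- cohort$status[keep] == stratum$disease
  r <- risks[keep]
  n_cases <- sum(is_case)
  n_controls <- sum(!is_case)
  if (n_cases == 0 || n_controls == 0) {
    stop("stratum must contain cases and controls")
  }
  curve <- do.call(rbind, lapply(grid, function(t) {
    fl <- flag_high_risk(r, t)
    ncf <- sum(fl & is_case)
    nkf <- sum(fl & !is_case)
    enr <- if (definition == "flagged-fraction") {
      (ncf / n_cases) / (nkf / n_controls)
    } else ncf / nkf
    data.frame(threshold = t, n_cases_flagged = ncf,
               n_controls_flagged = nkf, enrichment = enr)
  }))
  hit <- which(is.finite(curve$enrichment) & curve$enrichment >= target |
                 is.infinite(curve$enrichment) & curve$n_cases_flagged > 0)
  list(curve = curve,
       min_threshold = if (length(hit)) curve$threshold[min(hit)]
                       else NA_real_,
       target = target, definition = definition,
       n_cases = n_cases, n_controls = n_controls)
}

#' Uniquely-identified high-risk fractions across thresholds
#'
#' For each threshold and subgroup (controls and the stratum's cases), the
#' fraction of subjects flagged high-risk by exactly one of PRS, Gail, or
#' family history — the non-overlapping Venn segments expressed as
#' proportions.
#'
#' @param cohort a `cohort`.
#' @param risks_prs,risks_gail per-subject absolute risks, cohort order.
#' @param stratum a [stratum_spec()].
#' @param grid thresholds.
#' @return Long-format data frame: `threshold`, `subgroup`, `method`,
#'   `fraction`.
#' @export
unique_proportion_curves <- function(cohort, risks_prs, risks_gail, stratum,
                                     grid = threshold_grid()) {
  dat <- subset_stratum(cohort, stratum)
  idx <- match(dat$subject_id, cohort$subject_id)
  rp <- risks_prs[idx]
  rg <- risks_gail[idx]
  ff <- flag_family_history(dat)
  rows <- list()
  for (t in grid) {
    fp <- flag_high_risk(rp, t)
    fg <- flag_high_risk(rg, t)
    for (grp in unique(dat$status)) {
      g <- dat$status == grp
      seg <- venn_segments(fp[g], fg[g], ff[g])
      n <- sum(g)
      rows[[length(rows) + 1]] <- data.frame(
        threshold = t, subgroup = grp,
        method = c("PRS", "Gail", "FH"),
        fraction = unname(seg[c("PRS_only", "Gail_only", "FH_only")]) / n)
    }
  }
  do.call(rbind, rows)
}
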