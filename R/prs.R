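#' Read a PRS weight file
#'
#' Reads a PGS-Catalog-style scoring file: tab- or comma-delimited columns
#' `rsID`, `effect_allele`, `other_allele`, `effect_weight`, with `#` comment
#' lines. Column-name synonyms common in catalog exports are accepted.
#'
#' @param path file path.
#' @param delim field delimiter (default tab).
#' @return A `prs_weights` data frame with columns `id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @export
read_prs_weights <- function(path, delim = "\t") {
  df <- read.delim(path, sep = delim, comment.char = "#",
                   stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0) {
      stop("weight file missing a column among: ",
           paste(cands, collapse = ", "))
    }
    df[[hit[1]]]
  }
  out <- data.frame(
    id = as.character(pick(c("rsID", "rsid", "variant_id", "ID"))),
    effect_allele = toupper(pick(c("effect_allele", "A1"))),
    other_allele = toupper(pick(c("other_allele", "reference_allele", "A2"))),
    weight = as.numeric(pick(c("effect_weight", "weight", "beta"))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicate variant ids in weight file")
  if (any(!is.finite(out$weight))) stop("non-finite weights in weight file")
  structure(out, class = c("prs_weights", "data.frame"))
}

.is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Compute raw polygenic scores from a dosage matrix
#'
#' For each subject, the raw PRS is the weighted sum of effect-allele dosages
#' over the weight-file variants found in the dosage matrix. Missing dosage
#' entries are mean-imputed per variant with the mean observed dosage across
#' subjects (twice the effect-allele frequency in the dataset), matching the
#' behaviour of sum-score genotype scoring tools. When a dosage row's alleles
#' are swapped relative to the weight file, dosages are flipped (`2 - dose`).
#' Weight variants absent from the dosages are skipped and counted;
#' strand-ambiguous (A/T, C/G) variants are counted and kept or dropped per
#' `ambiguous`.
#'
#' @param dosages numeric matrix, variants in rows (rownames = variant ids),
#'   subjects in columns; entries in `[0, 2]` or `NA`.
#' @param weights a [read_prs_weights()] table.
#' @param dosage_alleles optional data frame (`id`, `effect_allele`,
#'   `other_allele`) describing the dosage rows; when omitted, dosages are
#'   assumed already expressed on the weight file's effect alleles.
#' @param ambiguous `"keep"` or `"drop"` strand-ambiguous variants.
#' @return Named numeric vector of raw scores (one per subject) with
#'   attributes `n_used`, `n_skipped`, `n_flipped`, `n_ambiguous`.
#' @export
score_prs <- function(dosages, weights, dosage_alleles = NULL,
                      ambiguous = c("keep", "drop")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)))
  w <- weights
  amb <- .is_ambiguous(w$effect_allele, w$other_allele)
  n_amb <- sum(amb & w$id %in% rownames(dosages))
  if (ambiguous == "drop") w <- w[!amb, , drop = FALSE]
  present <- w$id %in% rownames(dosages)
  n_skipped <- sum(!present)
  w <- w[present, , drop = FALSE]
  d <- dosages[w$id, , drop = FALSE]
  n_flipped <- 0L
  if (!is.null(dosage_alleles)) {
    da <- dosage_alleles[match(w$id, dosage_alleles$id), ]
    swapped <- toupper(da$effect_allele) == w$other_allele &
      toupper(da$other_allele) == w$effect_allele
    mismatch <- !swapped & toupper(da$effect_allele) != w$effect_allele
    if (any(mismatch, na.rm = TRUE)) {
      stop("allele mismatch (not a swap) for variant(s): ",
           paste(w$id[which(mismatch)], collapse = ", "))
    }
    if (any(swapped)) {
      d[swapped, ] <- 2 - d[swapped, , drop = FALSE]
      n_flipped <- sum(swapped)
    }
  }
  # per-variant mean imputation of missing entries
  if (anyNA(d)) {
    vm <- rowMeans(d, na.rm = TRUE)
    vm[is.nan(vm)] <- 0
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- vm[na_idx[, 1]]
  }
  raw <- as.numeric(crossprod(d, w$weight))
  names(raw) <- colnames(dosages)
  structure(raw, n_used = nrow(w), n_skipped = n_skipped,
            n_flipped = n_flipped, n_ambiguous = n_amb)
}

#' Read a variant x subject dosage matrix from a VCF with DS genotype field
#'
#' @param path VCF path (uncompressed or gzipped).
#' @return list with `dosages` (matrix) and `alleles` (data frame `id`,
#'   `effect_allele` = ALT, `other_allele` = REF).
#' @export
read_dosages_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  rownames(ds) <- fix[, "ID"]
  list(dosages = ds,
       alleles = data.frame(id = fix[, "ID"],
                            effect_allele = fix[, "ALT"],
                            other_allele = fix[, "REF"],
                            stringsAsFactors = FALSE))
}

#' PRS standardization and conversion parameters
#'
#' `mu_ctrl` and `sd_ctrl` are the ancestry-specific control mean and
#' standard deviation of the raw score (standardization is always against
#' controls, then applied to everyone). `beta` is the log odds ratio per
#' standard deviation of PRS; the default transcribes the per-SD OR of 1.61
#' reported for the 313-variant breast cancer PRS in its development paper.
#' `band` is the percentile interval treated as the general population in the
#' theoretical-OR conversion (default the 40th-60th percentile).
#'
#' @param mu_ctrl,sd_ctrl control mean and SD of the raw score (`sd_ctrl` > 0).
#' @param beta log OR per SD of PRS.
#' @param band numeric length-2 percentile interval in `[0, 1]`.
#' @return A `prs_params` list.
#' @export
prs_params <- function(mu_ctrl = 0, sd_ctrl = 1, beta = log(1.61),
                       band = c(0.4, 0.6)) {
  if (sd_ctrl <= 0) stop("sd_ctrl must be > 0")
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= 1)) {
    stop("band must satisfy 0 <= lo < hi <= 1")
  }
  structure(list(mu_ctrl = mu_ctrl, sd_ctrl = sd_ctrl, beta = beta,
                 band = band), class = "prs_params")
}

#' Estimate control-based standardization parameters from a cohort
#' @param raw raw scores.
#' @param is_control logical vector.
#' @inheritParams prs_params
#' @export
estimate_prs_params <- function(raw, is_control, beta = log(1.61),
                                band = c(0.4, 0.6)) {
  prs_params(mean(raw[is_control], na.rm = TRUE),
             sd(raw[is_control], na.rm = TRUE), beta, band)
}

#' Standardize raw scores and convert to percentiles
#'
#' `z = (raw - mu_ctrl) / sd_ctrl`; the percentile is the standard normal CDF
#' at `z` (the distributional convention; empirical-rank percentiles are
#' available via `empirical = TRUE`).
#'
#' @param raw raw scores.
#' @param params a [prs_params()].
#' @param empirical use empirical ranks instead of the normal CDF.
#' @return data frame with columns `z`, `pct`.
#' @export
standardize_prs <- function(raw, params, empirical = FALSE) {
  z <- (raw - params$mu_ctrl) / params$sd_ctrl
  pct <- if (empirical) rank(z, ties.method = "average") / (length(z) + 1)
         else pnorm(z)
  data.frame(z = z, pct = pct)
}

# Mean of exp(beta * U) phi(u) over [qnorm(lo), qnorm(hi)], normalized by the
# band mass: closed form via the Gaussian tilt identity.
.band_mean_rr <- function(beta, band) {
  exp(beta^2 / 2) *
    (pnorm(qnorm(band[2]) - beta) - pnorm(qnorm(band[1]) - beta)) /
    (band[2] - band[1])
}

#' Theoretical relative risk versus the middle-quintile band
#'
#' Converts a standardized PRS into a relative risk against the general
#' population, represented by the 40th-60th percentile band:
#' `rr(z) = exp(beta z) / c` with `c` the average of `exp(beta u)` over the
#' band under the standard normal density (closed form, no quadrature).
#'
#' @param z standardized score(s).
#' @param params a [prs_params()].
#' @return Numeric relative risks (> 0); identically 1 when `beta = 0`.
#' @export
rr_vs_middle_quintile <- function(z, params) {
  exp(params$beta * z) / .band_mean_rr(params$beta, params$band)
}

#' Population mean of the PRS relative risk
#'
#' `E[rr(Z)]` over standard-normal `Z`: `exp(beta^2/2) / c`. Dividing the
#' population incidence hazard by this mean gives the PRS baseline hazard
#' under which the population-average incidence is conserved.
#'
#' @param params a [prs_params()].
#' @export
prs_mean_rr <- function(params) {
  exp(params$beta^2 / 2) / .band_mean_rr(params$beta, params$band)
}

#' PRS five-year absolute risk
#'
#' Projects the PRS relative risk to absolute risk against the population
#' rate table. Under the default `"population-mean"` baseline, the incidence
#' hazard is divided by `E[rr(Z)]` so the population-average incidence is
#' reproduced; the alternative `"mid-quintile"` baseline treats the middle
#' band as carrying the raw population incidence. No attributable-risk
#' adjustment is applied (the PRS baseline is handled by this constraint).
#'
#' @param z standardized score(s).
#' @param age age(s) in years.
#' @param params a [prs_params()].
#' @param rates a [rate_table()].
#' @param horizon years (default 5).
#' @param baseline `"population-mean"` or `"mid-quintile"`.
#' @return data frame with `z`, `pct`, `rr`, `ar5`.
#' @export
prs_five_year_risk <- function(z, age, params, rates, horizon = 5,
                               baseline = c("population-mean",
                                            "mid-quintile")) {
  baseline <- match.arg(baseline)
  rr <- rr_vs_middle_quintile(z, params)
  rr_eff <- if (baseline == "population-mean") rr / prs_mean_rr(params)
            else rr
  ar5 <- project_absolute_risk(rates, age, rr_eff, horizon,
                               use_AR_adjustment = FALSE)
  data.frame(z = z, pct = pnorm(z), rr = rr, ar5 = ar5)
}

#' Score a cohort with the PRS engine
#'
#' Standardizes the cohort's raw PRS against ancestry-specific control means
#' and SDs, converts to percentile and theoretical relative risk, projects to
#' five-year absolute risk with the ancestry-mapped rate table, and appends
#' `prs_z`, `prs_pct`, `prs_ar5` columns.
#'
#' @param cohort a `cohort` with a `prs_raw` column (or supply `raw`).
#' @param raw optional named raw-score vector overriding `prs_raw`.
#' @param beta log OR per SD of PRS.
#' @param band percentile band treated as the general population.
#' @param rates named list of rate tables keyed by ancestry.
#' @param baseline see [prs_five_year_risk()].
#' @param horizon years.
#' @return The input `cohort` with `prs_z`, `prs_pct`, `prs_ar5` appended.
#' @export
score_prs_cohort <- function(cohort, raw = NULL, beta = log(1.61),
                             band = c(0.4, 0.6),
                             rates = default_rates_map(),
                             baseline = "population-mean", horizon = 5) {
  if (!is.null(raw)) cohort$prs_raw <- unname(raw[cohort$subject_id])
  if (all(is.na(cohort$prs_raw))) stop("cohort has no raw PRS to score")
  cohort$prs_z <- NA_real_
  cohort$prs_pct <- NA_real_
  cohort$prs_ar5 <- NA_real_
  for (anc in unique(cohort$ancestry)) {
    idx <- which(cohort$ancestry == anc & !is.na(cohort$prs_raw))
    if (length(idx) == 0) next
    params <- estimate_prs_params(cohort$prs_raw[idx],
                                  cohort$status[idx] == "control",
                                  beta, band)
    std <- standardize_prs(cohort$prs_raw[idx], params)
    res <- prs_five_year_risk(std$z, cohort$age[idx], params,
                              rates[[anc]], horizon, baseline)
    cohort$prs_z[idx] <- res$z
    cohort$prs_pct[idx] <- res$pct
    cohort$prs_ar5[idx] <- res$ar5
  }
  .log_step(cohort, sprintf(
    "score_prs_cohort: %s baseline, beta=%.4f, %d subjects scored",
    baseline, beta, sum(!is.na(cohort$prs_z))))
}
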