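#' @importFrom stats pnorm qnorm rnorm rbinom runif quantile sd glm binomial
#'   coef vcov integrate ks.test binom.test plogis qlogis setNames
#' @importFrom utils read.delim write.table modifyList
NULL

# Declared categorical levels of the subject table. "unknown" is a real level:
# after parsing no Gail covariate may be an empty cell.
.cohort_levels <- list(
  ancestry             = c("European", "Asian"),
  status               = c("control", "invasive", "DCIS"),
  control_source       = c("population", "other", "not_applicable"),
  age_menarche         = c("lt12", "12to13", "ge14", "unknown"),
  age_first_birth      = c("nulliparous", "lt20", "20to24", "25to29", "ge30",
                           "unknown"),
  n_relatives          = c("0", "1", "ge2", "unknown"),
  n_biopsies           = c("0", "1", "ge2", "unknown"),
  atypical_hyperplasia = c("no", "yes", "unknown")
)

# Gail covariates subject to missing-value recoding (the hyperplasia flag has
# its own dedicated no-effect "unknown" level in the relative-risk engine).
.gail_recoded <- c("age_menarche", "age_first_birth", "n_relatives",
                   "n_biopsies")

.cohort_columns <- c("subject_id", "study_id", "ancestry", "age", "status",
                     "control_source", names(.cohort_levels)[-(1:3)],
                     "prs_raw")

#' Construct a cohort object
#'
#' A cohort is a data frame of subjects (one row each) carrying a provenance
#' log of the filters that produced it. Categorical fields are stored as
#' character vectors restricted to their declared levels; `"unknown"` is a
#' level, never an empty cell.
#'
#' @param subjects data frame with columns `subject_id`, `study_id`,
#'   `ancestry`, `age`, `status`, `control_source`, `age_menarche`,
#'   `age_first_birth`, `n_relatives`, `n_biopsies`, `atypical_hyperplasia`
#'   and optionally `prs_raw`.
#' @param provenance character vector of log lines.
#' @return An object of class `cohort` (a data frame).
#' @export
new_cohort <- function(subjects, provenance = character()) {
  stopifnot(is.data.frame(subjects))
  missing_cols <- setdiff(setdiff(.cohort_columns, "prs_raw"),
                          names(subjects))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"prs_raw" %in% names(subjects)) subjects$prs_raw <- NA_real_
  for (col in names(.cohort_levels)) {
    vals <- as.character(subjects[[col]])
    bad <- !is.na(vals) & !vals %in% .cohort_levels[[col]]
    if (any(bad)) {
      stop(sprintf("column '%s' has undeclared level(s): %s", col,
                   paste(unique(vals[bad]), collapse = ", ")))
    }
    subjects[[col]] <- vals
  }
  if (anyDuplicated(subjects$subject_id)) stop("subject_id must be unique")
  structure(subjects, class = c("cohort", "data.frame"),
            provenance = provenance)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d controls, %d invasive, %d DCIS)\n",
              nrow(x), sum(x$status == "control"),
              sum(x$status == "invasive"), sum(x$status == "DCIS")))
  log <- attr(x, "provenance")
  if (length(log) > 0) cat("provenance:\n", paste(" -", log, collapse = "\n"),
                           "\n")
  invisible(x)
}

#' Provenance log of a cohort
#' @param cohort a `cohort` object.
#' @return Character vector of filter-log lines.
#' @export
provenance <- function(cohort) attr(cohort, "provenance")

.log_step <- function(cohort, line) {
  attr(cohort, "provenance") <- c(attr(cohort, "provenance"), line)
  cohort
}

# Subsetting a cohort keeps class and provenance.
#' @export
`[.cohort` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    structure(out, class = c("cohort", "data.frame"),
              provenance = attr(x, "provenance"))
  } else out
}

#' Read a phenotype table
#'
#' Parses a delimited subject table into a [new_cohort()] object. Unknown-value
#' codes (consortium files vary) are declared via `unknown_codes` and mapped to
#' the `"unknown"` level of each categorical Gail covariate. A value that is
#' neither a declared level nor a declared unknown code is an error, never a
#' silent coercion.
#'
#' @param path file path to a UTF-8 delimited text file with a header row.
#' @param delim field delimiter (default tab).
#' @param unknown_codes character vector of codes mapped to `"unknown"`.
#' @return A `cohort`.
#' @export
read_phenotypes <- function(path, delim = "\t",
                            unknown_codes = c("", "NA", "unknown",
                                              "888", "999")) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- read.delim(path, sep = delim, colClasses = "character",
                    na.strings = NULL, check.names = FALSE)
  mandatory <- setdiff(.cohort_columns, c("prs_raw", "control_source"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("phenotype file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  # control_source defaults to population when absent, so the
  # population-based-control sensitivity subset stays available
  if (!"control_source" %in% names(raw)) {
    raw$control_source <- ifelse(raw$status == "control", "population",
                                 "not_applicable")
  }
  for (col in setdiff(names(.cohort_levels), c("ancestry", "status"))) {
    raw[[col]][raw[[col]] %in% unknown_codes] <- "unknown"
  }
  age_chr <- trimws(raw$age)
  age <- suppressWarnings(as.numeric(age_chr))
  unparseable <- is.na(age) & !age_chr %in% unknown_codes
  if (any(unparseable)) {
    stop("non-numeric age for subject(s): ",
         paste(raw$subject_id[unparseable], collapse = ", "))
  }
  raw$age <- age
  if ("prs_raw" %in% names(raw)) {
    raw$prs_raw <- suppressWarnings(as.numeric(raw$prs_raw))
  }
  cohort <- new_cohort(raw)
  .log_step(cohort, sprintf("read %d subjects from %s", nrow(raw),
                            basename(path)))
}

#' Write a cohort (with any appended risk columns) back to delimited text
#' @param cohort a `cohort`.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_phenotypes <- function(cohort, path, delim = "\t") {
  write.table(as.data.frame(cohort), path, sep = delim, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Individual-level inclusion filter
#'
#' Retains subjects with known age in `[min_age, max_age]`, the validity range
#' of Gail five-year prediction. Removal counts are recorded by reason in the
#' provenance log, split by disease status (age at interview for controls, age
#' at diagnosis for cases).
#'
#' @param cohort a `cohort`.
#' @param min_age,max_age inclusive age bounds in years.
#' @return Filtered `cohort`; `|input| = |output| +` logged removals.
#' @export
filter_individuals <- function(cohort, min_age = 30, max_age = 80) {
  unknown_age <- is.na(cohort$age)
  n_unk_ctrl <- sum(unknown_age & cohort$status == "control")
  n_unk_case <- sum(unknown_age & cohort$status != "control")
  too_young <- !unknown_age & cohort$age < min_age
  too_old <- !unknown_age & cohort$age > max_age
  keep <- !unknown_age & !too_young & !too_old
  out <- cohort[keep, , drop = FALSE]
  out <- .log_step(out, sprintf(
    "filter_individuals: removed %d unknown-age controls, %d unknown-age cases, %d aged <%d, %d aged >%d",
    n_unk_ctrl, n_unk_case, sum(too_young), min_age, sum(too_old), max_age))
  out
}

#' Study-level exclusion filter
#'
#' Within each (study x disease-status) cell, computes the fraction of
#' subjects with `"unknown"` values for each of the three core Gail factors
#' (age at menarche, age at first live birth, first-degree family history) and
#' drops the cell when at least two of the three fractions are >= 0.5
#' (boundary counted). Exclusion is determined separately per study and per
#' disease status. Only declared `"unknown"` levels count towards the
#' fractions; structurally absent columns are a parse error upstream, and the
#' distinction is noted in the provenance log.
#'
#' @param cohort a `cohort`.
#' @return Filtered `cohort` with dropped cells logged.
#' @export
filter_studies <- function(cohort) {
  vars <- c("age_menarche", "age_first_birth", "n_relatives")
  cell <- interaction(cohort$study_id, cohort$status, drop = TRUE, sep = "|")
  drop_cell <- vapply(levels(cell), function(lv) {
    rows <- cell == lv
    frac <- vapply(vars, function(v) mean(cohort[[v]][rows] == "unknown"),
                   numeric(1))
    sum(frac >= 0.5) >= 2
  }, logical(1))
  dropped <- levels(cell)[drop_cell]
  keep <- !(as.character(cell) %in% dropped)
  out <- cohort[keep, , drop = FALSE]
  msg <- if (length(dropped) == 0) {
    "filter_studies: no study/status cells dropped"
  } else {
    sprintf("filter_studies: dropped %d subjects from cell(s) %s (>=2 of 3 core factors >=50%% unknown among declared levels)",
            sum(!keep), paste(dropped, collapse = ", "))
  }
  .log_step(out, msg)
}

#' Missing-data recoding policy
#'
#' `baseline` maps every unknown Gail covariate to its lowest-relative-risk
#' (reference) category, the primary-analysis convention; `highest_risk` maps
#' unknowns to the highest-relative-risk category of each variable, the
#' sensitivity-analysis convention. The highest-risk category for age at first
#' birth is the argmax of the packaged log relative-risk coefficients
#' (ties resolved to the later-listed category), which for the shipped
#' coefficient table is `ge30`.
#'
#' @param mode `"baseline"` or `"highest_risk"`.
#' @return A `missing_policy` object.
#' @export
missing_policy <- function(mode = c("baseline", "highest_risk")) {
  mode <- match.arg(mode)
  map <- if (mode == "baseline") {
    c(age_menarche = "ge14", age_first_birth = "lt20",
      n_relatives = "0", n_biopsies = "0")
  } else {
    c(age_menarche = "lt12", age_first_birth = "ge30",
      n_relatives = "ge2", n_biopsies = "ge2")
  }
  structure(list(mode = mode, map = map), class = "missing_policy")
}

#' Apply a missing-data policy to a cohort
#'
#' Returns a copy in which every `"unknown"` among the four recoded Gail
#' covariates is replaced per the policy. Known values are never changed. The
#' atypical-hyperplasia flag is not recoded: its `"unknown"` level carries a
#' no-effect multiplier of 1 in the relative-risk engine.
#'
#' @param cohort a `cohort`.
#' @param policy a [missing_policy()].
#' @return Recoded `cohort`.
#' @export
apply_missing_policy <- function(cohort, policy) {
  stopifnot(inherits(policy, "missing_policy"))
  n_recoded <- 0L
  for (v in .gail_recoded) {
    unk <- cohort[[v]] == "unknown"
    n_recoded <- n_recoded + sum(unk)
    cohort[[v]][unk] <- policy$map[[v]]
  }
  .log_step(cohort, sprintf("apply_missing_policy(%s): recoded %d unknowns",
                            policy$mode, n_recoded))
}
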