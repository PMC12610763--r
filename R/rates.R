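#' Age-banded hazard rate table
#'
#' A rate table holds, per age band `[age_start, age_end)`, the breast-cancer
#' incidence hazard `h1` (per person-year), the competing (non-breast-cancer)
#' mortality hazard `h2`, and the attributable-risk complement `one_minus_AR`
#' that converts composite population incidence into baseline incidence for
#' all-reference-covariate women in Gail-type models. Bands must be
#' contiguous, non-overlapping, and cover at least ages 20-90.
#'
#' @param df data frame with columns `population`, `age_start`, `age_end`,
#'   `h1`, `h2`, `one_minus_AR`.
#' @return A `rate_table` object.
#' @export
rate_table <- function(df) {
  needed <- c("population", "age_start", "age_end", "h1", "h2",
              "one_minus_AR")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("rate table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$age_start), needed]
  if (any(df$age_end <= df$age_start)) stop("empty or inverted age band")
  if (nrow(df) > 1 &&
      any(abs(df$age_start[-1] - df$age_end[-nrow(df)]) > 1e-9)) {
    stop("rate table bands must be contiguous and non-overlapping")
  }
  if (df$age_start[1] > 20 || df$age_end[nrow(df)] < 90) {
    stop("rate table must cover at least ages [20, 90)")
  }
  if (any(df$h1 < 0) || any(df$h2 < 0)) stop("hazards must be non-negative")
  if (any(df$one_minus_AR <= 0 | df$one_minus_AR > 1)) {
    stop("one_minus_AR must be in (0, 1]")
  }
  structure(df, class = c("rate_table", "data.frame"))
}

#' Read a rate table from delimited text
#' @param path file with columns population, age_start, age_end, h1, h2,
#'   one_minus_AR.
#' @param delim field delimiter.
#' @export
read_rate_table <- function(path, delim = "\t") {
  rate_table(read.delim(path, sep = delim))
}

#' Packaged synthetic rate tables
#'
#' Returns one of the two rate tables shipped with the package, labelled
#' `"White"` and `"Chinese"`. These are synthetic stand-ins constructed to
#' have the magnitude and age-shape of US White and urban Chinese female
#' breast-cancer incidence and all-cause non-breast mortality (5-year bands,
#' ages 20-90); they are not transcriptions of any registry table and any
#' user-supplied table can be substituted. The `one_minus_AR` column carries
#' the published Gail model 2 attributable-risk complements (two age regimes,
#' <50 / >=50).
#'
#' @param population `"White"` or `"Chinese"`.
#' @return A `rate_table`.
#' @export
default_rate_table <- function(population = c("White", "Chinese")) {
  population <- match.arg(population)
  file <- system.file("extdata",
                      sprintf("rates_%s_synthetic.tsv", tolower(population)),
                      package = "riskoverlap", mustWork = TRUE)
  read_rate_table(file)
}

#' Project a relative risk to an absolute risk over a horizon
#'
#' Converts a relative risk into an absolute risk of disease over
#' `[age, age + horizon)` under piecewise-constant cause-specific hazards with
#' competing mortality. Within each rate band intersected with the horizon,
#' the contribution is closed-form:
#' \deqn{S_k \frac{r h^*_{1k}}{r h^*_{1k} + h_{2k}}
#'       \left(1 - e^{-(r h^*_{1k} + h_{2k}) L_k}\right)}
#' where \eqn{h^*_{1k} = h_{1k}(1 - AR_k)} when `use_AR_adjustment` is set
#' (Gail-type baseline hazard) and \eqn{h^*_{1k} = h_{1k}} otherwise, `L_k`
#' is the sub-band length and \eqn{S_k} the probability of remaining free of
#' both events at the band start. Exact for banded tables; no quadrature.
#'
#' @param rates a [rate_table()].
#' @param age current age(s) in years; `age + horizon` must lie inside the
#'   table coverage.
#' @param rr relative risk(s), > 0; recycled against `age`.
#' @param horizon projection horizon in years (default 5).
#' @param use_AR_adjustment multiply `h1` by `one_minus_AR` (Gail engine
#'   convention); the PRS engine instead handles its baseline via the
#'   population-mean constraint and leaves this off.
#' @return Numeric vector of absolute risks in `[0, 1]`.
#' @export
project_absolute_risk <- function(rates, age, rr, horizon = 5,
                                  use_AR_adjustment = TRUE) {
  stopifnot(inherits(rates, "rate_table"), horizon > 0)
  n <- max(length(age), length(rr))
  age <- rep_len(as.numeric(age), n)
  rr <- rep_len(as.numeric(rr), n)
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("relative risk must be finite and > 0")
  }
  lo <- rates$age_start[1]
  hi <- rates$age_end[nrow(rates)]
  if (any(age < lo) || any(age + horizon > hi + 1e-9)) {
    stop(sprintf("age window outside rate-table coverage [%g, %g)", lo, hi))
  }
  h1s <- rates$h1 * if (use_AR_adjustment) rates$one_minus_AR else 1
  surv <- rep(1, n)
  ar <- rep(0, n)
  for (k in seq_len(nrow(rates))) {
    L <- pmax(0, pmin(rates$age_end[k], age + horizon) -
                   pmax(rates$age_start[k], age))
    lam <- rr * h1s[k] + rates$h2[k]
    active <- L > 0 & lam > 0
    if (any(active)) {
      dec <- exp(-lam[active] * L[active])
      ar[active] <- ar[active] + surv[active] *
        (rr[active] * h1s[k] / lam[active]) * (1 - dec)
      surv[active] <- surv[active] * dec
    }
  }
  ar
}
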