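#' Model-based ROC curve
#'
#' The ROC curve a set of predicted risks would achieve if they were
#' perfectly calibrated: with subjects ordered by descending predicted risk
#' `pi` and a cut `c` sweeping the distinct values,
#' `TPR(c) = sum(pi_i >= c) pi_i / sum pi_i` and
#' `FPR(c) = sum(pi_i >= c) (1 - pi_i) / sum(1 - pi_i)`. Divergence between
#' this curve and the empirical ROC indicates miscalibration independent of
#' the sample's case mix. The returned curve includes (0, 0) and (1, 1).
#'
#' @param predicted per-subject risks in `[0, 1]`.
#' @return A `roc_curve` data frame with columns `fpr`, `tpr`.
#' @export
model_based_roc <- function(predicted) {
  if (any(!is.finite(predicted)) || any(predicted < 0 | predicted > 1)) {
    stop("predicted risks must be finite and in [0, 1]")
  }
  s1 <- sum(predicted)
  s0 <- sum(1 - predicted)
  if (s1 == 0 || s0 == 0) {
    stop("degenerate input: predicted risks are all 0 or all 1")
  }
  p <- sort(predicted, decreasing = TRUE)
  tpr <- cumsum(p) / s1
  fpr <- cumsum(1 - p) / s0
  last <- cumsum(rle(p)$lengths)  # one point per distinct cut value
  structure(data.frame(fpr = c(0, fpr[last]), tpr = c(0, tpr[last])),
            class = c("roc_curve", "data.frame"))
}

#' Empirical ROC curve
#'
#' Standard ROC over the distinct score cuts, tied scores included
#' simultaneously.
#'
#' @param scores per-subject risk scores.
#' @param labels 0/1 outcomes; both classes must be present.
#' @return A `roc_curve` data frame with columns `fpr`, `tpr`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tpr <- cumsum(y) / n1
  fpr <- cumsum(1 - y) / n0
  last <- cumsum(rle(scores[ord])$lengths)
  structure(data.frame(fpr = c(0, fpr[last]), tpr = c(0, tpr[last])),
            class = c("roc_curve", "data.frame"))
}

# Evaluate a (step-function) ROC curve's TPR at given FPR values:
# the highest TPR attained at FPR <= f.
.roc_tpr_at <- function(curve, fpr) {
  tpr_max <- cummax(curve$tpr)
  idx <- findInterval(fpr + 1e-12, curve$fpr)
  ifelse(idx == 0, 0, tpr_max[pmax(idx, 1)])
}

#' Supremum vertical distance between two ROC curves
#' @param a,b `roc_curve` objects.
#' @return Max absolute TPR difference over the union of FPR breakpoints.
#' @export
roc_sup_distance <- function(a, b) {
  grid <- sort(unique(c(a$fpr, b$fpr)))
  grid <- unique(c(grid, pmax(grid - 1e-9, 0)))
  max(abs(.roc_tpr_at(a, grid) - .roc_tpr_at(b, grid)))
}

#' Calibration tests against the model-based ROC
#'
#' Three tests of whether predicted risks `pi` are compatible with observed
#' case-control outcomes:
#' \describe{
#'   \item{mean calibration}{`T = (sum y - sum pi) / sqrt(sum pi (1 - pi))`
#'     against a standard normal reference: is the expected event count
#'     right? When the observed event fraction equals the mean predicted
#'     risk, `T = 0` and `p = 1`.}
#'   \item{ROC equality}{statistic `D` = supremum vertical distance between
#'     the empirical ROC and the model-based ROC; its null distribution is
#'     obtained by a parametric bootstrap that regenerates outcomes as
#'     independent Bernoulli(`pi`).}
#'   \item{unified}{a joint min-p combination of the two component
#'     statistics, calibrated against the same bootstrap null.}
#' }
#' The observed event rate in a case-control sample does not represent the
#' population prevalence, so these tests speak to calibration relative to
#' the supplied sample's case mix; predicted risks must be re-based before
#' making population-level calibration claims.
#'
#' @param predicted per-subject risks in `(0, 1)`.
#' @param labels 0/1 outcomes.
#' @param n_boot bootstrap resamples (>= 200).
#' @param seed integer seed, fixed and recorded in the output.
#' @param tests `"all"`, or `"mean"` for the analytic mean-calibration test
#'   alone (no bootstrap; the ROC-equality and unified p-values are `NA`).
#' @return An `mroc_result` list: the two curves, `p_mean`,
#'   `p_roc_equality`, `p_unified`, statistics, and metadata (`n_boot`,
#'   `seed`, method notes).
#' @export
calibration_tests <- function(predicted, labels, n_boot = 1000,
                              seed = 1L, tests = c("all", "mean")) {
  tests <- match.arg(tests)
  if (n_boot < 200) stop("n_boot must be at least 200")
  labels <- as.integer(labels)
  emp <- empirical_roc(predicted, labels)
  mod <- model_based_roc(predicted)
  v <- sum(predicted * (1 - predicted))
  t_obs <- (sum(labels) - sum(predicted)) / sqrt(v)
  p_mean <- 2 * pnorm(-abs(t_obs))
  if (tests == "mean") {
    return(structure(list(empirical_roc = emp, model_roc = mod,
                          statistic_mean = t_obs, statistic_roc = NA_real_,
                          p_mean = p_mean, p_roc_equality = NA_real_,
                          p_unified = NA_real_, n_boot = 0L, seed = seed,
                          method = "mean calibration only (analytic)"),
                     class = "mroc_result"))
  }
  # the sup-distance statistic is evaluated on the model curve's FPR
  # breakpoints (and their left limits), identically for the observed data
  # and every bootstrap draw
  n <- length(predicted)
  ord <- order(predicted, decreasing = TRUE)
  ps <- predicted[ord]
  last <- cumsum(rle(ps)$lengths)
  grid <- sort(c(mod$fpr, pmax(mod$fpr - 1e-9, 0)))
  mod_at <- .roc_tpr_at(mod, grid)
  sup_d <- function(y_ord) {
    cy <- cumsum(y_ord)
    n1 <- cy[n]
    if (n1 == 0L || n1 == n) return(1)
    tpr <- cy[last] / n1
    fpr <- (last - cy[last]) / (n - n1)
    idx <- findInterval(grid + 1e-12, c(0, fpr))
    max(abs(c(0, tpr)[idx] - mod_at))
  }
  d_obs <- sup_d(labels[ord])
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  t_boot <- numeric(n_boot)
  d_boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    yb <- rbinom(n, 1L, ps)
    t_boot[b] <- (sum(yb) - sum(ps)) / sqrt(v)
    d_boot[b] <- sup_d(yb)
  }
  p_roc <- (1 + sum(d_boot >= d_obs)) / (n_boot + 1)
  # min-p combination: each bootstrap statistic gets its empirical p within
  # the bootstrap sample; the unified p compares the observed min-p to the
  # bootstrap distribution of min-p
  p_t_of <- function(t) (1 + sum(abs(t_boot) >= abs(t))) / (n_boot + 1)
  p_d_of <- function(d) (1 + sum(d_boot >= d)) / (n_boot + 1)
  minp_obs <- min(p_t_of(t_obs), p_d_of(d_obs))
  rt <- rank(-abs(t_boot), ties.method = "max")   # count of >= within boot
  rd <- rank(-d_boot, ties.method = "max")        # (each includes itself)
  minp_boot <- pmin(rt / (n_boot + 1), rd / (n_boot + 1))
  p_unified <- (1 + sum(minp_boot <= minp_obs)) / (n_boot + 1)
  structure(list(empirical_roc = emp, model_roc = mod,
                 statistic_mean = t_obs, statistic_roc = d_obs,
                 p_mean = p_mean, p_roc_equality = p_roc,
                 p_unified = p_unified,
                 n_boot = n_boot, seed = seed,
                 method = paste("mean: normal reference on summed Bernoulli",
                                "variance; ROC equality & unified:",
                                "parametric bootstrap, outcomes ~",
                                "Bernoulli(predicted)")),
            class = "mroc_result")
}

#' @export
print.mroc_result <- function(x, ...) {
  cat(sprintf(
    "mROC calibration: p_mean = %.3g, p_roc_equality = %.3g, p_unified = %.3g\n",
    x$p_mean, x$p_roc_equality, x$p_unified))
  cat(sprintf("  (sup ROC distance %.4f; %d bootstrap resamples, seed %d)\n",
              x$statistic_roc, x$n_boot, x$seed))
  invisible(x)
}

#' Decile calibration table
#'
#' Partitions subjects into deciles of predicted risk (sizes differing by at
#' most one) and reports, per decile, the mean predicted risk and the
#' observed event fraction with an exact binomial 95% interval. A constant
#' prediction vector collapses to a single effective group and is flagged.
#'
#' @param predicted per-subject risks.
#' @param labels 0/1 outcomes.
#' @param n_groups number of groups (default 10).
#' @return data frame: `decile`, `n`, `mean_predicted`, `observed`,
#'   `obs_lo`, `obs_hi`; attribute `degenerate` when predictions are
#'   constant.
#' @export
decile_calibration <- function(predicted, labels, n_groups = 10) {
  n <- length(predicted)
  if (n < 20) stop("decile calibration needs at least 20 subjects")
  labels <- as.integer(labels)
  ord <- order(predicted)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * n_groups / n)
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    i <- grp == g
    ci <- binom.test(sum(labels[i]), sum(i))$conf.int
    data.frame(decile = g, n = sum(i), mean_predicted = mean(predicted[i]),
               observed = mean(labels[i]), obs_lo = ci[1], obs_hi = ci[2])
  }))
  attr(out, "degenerate") <- length(unique(predicted)) == 1
  out
}
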