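# Small in-code fixtures shared across tests.

# a minimal valid subject row, overridable field by field
toy_subject <- function(id = "S1", ...) {
  base <- list(subject_id = id, study_id = "ST1", ancestry = "European",
               age = 55, status = "control", control_source = "population",
               age_menarche = "ge14", age_first_birth = "lt20",
               n_relatives = "0", n_biopsies = "0",
               atypical_hyperplasia = "no", prs_raw = 0)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

toy_cohort <- function(rows) {
  new_cohort(do.call(rbind, rows))
}

# single-band rate table for closed-form projection checks
flat_rates <- function(h1 = 0.01, h2 = 0, omar = 1) {
  rate_table(data.frame(population = "toy", age_start = 20, age_end = 90,
                        h1 = h1, h2 = h2, one_minus_AR = omar))
}

# random multi-band rate table over [20, 90)
random_rate_table <- function() {
  starts <- seq(20, 85, by = 5)
  rate_table(data.frame(population = "rnd", age_start = starts,
                        age_end = starts + 5,
                        h1 = runif(length(starts), 1e-5, 5e-3),
                        h2 = runif(length(starts), 1e-5, 2e-2),
                        one_minus_AR = runif(length(starts), 0.3, 1)))
}

# independent fine-grained integrator of the two-state survival ODE:
# dS/dt = -(r h1* + h2) S, risk accrues at rate r h1* S
ode_absolute_risk <- function(rates, age, rr, horizon = 5,
                              use_AR_adjustment = TRUE) {
  h1s <- rates$h1 * if (use_AR_adjustment) rates$one_minus_AR else 1
  hazard1 <- function(t) {
    idx <- findInterval(t, rates$age_start)
    rr * h1s[idx]
  }
  hazard2 <- function(t) {
    idx <- findInterval(t, rates$age_start)
    rates$h2[idx]
  }
  deriv <- function(t, y, parms) {
    list(c(-(hazard1(t) + hazard2(t)) * y[1], hazard1(t) * y[1]))
  }
  # integrate band-piece by band-piece so the discontinuities are respected
  cuts <- sort(unique(c(age, age + horizon,
                        rates$age_start[rates$age_start > age &
                                          rates$age_start < age + horizon])))
  y <- c(S = 1, F = 0)
  for (i in seq_len(length(cuts) - 1)) {
    mid <- (cuts[i] + cuts[i + 1]) / 2
    sol <- deSolve::lsoda(y, c(cuts[i], cuts[i + 1]),
                          function(t, y, p) {
                            l1 <- hazard1(mid); l2 <- hazard2(mid)
                            list(c(-(l1 + l2) * y[1], l1 * y[1]))
                          }, parms = NULL, rtol = 1e-12, atol = 1e-14)
    y <- sol[nrow(sol), c("S", "F")]
  }
  unname(y["F"])
}

# brute-force pairwise AUC (ties count one half)
pairwise_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (x in cases) tot <- tot + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  tot / (length(cases) * length(ctrls))
}

# trapezoid area under a roc_curve (exact for step/segment curves)
roc_area <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  f <- curve$fpr[o]; t <- curve$tpr[o]
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

# brute-force per-subject PRS scoring loop with the same imputation rule
loop_score_prs <- function(dosages, weights) {
  ids <- intersect(weights$id, rownames(dosages))
  out <- numeric(ncol(dosages))
  for (j in seq_len(ncol(dosages))) {
    s <- 0
    for (id in ids) {
      d <- dosages[id, j]
      if (is.na(d)) d <- mean(dosages[id, ], na.rm = TRUE)
      s <- s + weights$weight[weights$id == id] * d
    }
    out[j] <- s
  }
  out
}
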