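---
title: "Methods: risk projection, stratification overlap, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk projection, stratification overlap, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskoverlap)
```

This vignette is the package's account of its statistical machinery: the
two absolute-risk engines, the evaluation and calibration methodology, the
high-risk overlap analysis, the synthetic cohort generator, and the design
choices made where more than one defensible construction existed.

## The two-hazard absolute-risk projector

Both risk engines reduce to one primitive: convert a relative risk $r$ into
an absolute probability of breast cancer over $[a, a+h)$ under competing
mortality. We assume piecewise-constant cause-specific hazards on the bands
of a rate table — breast-cancer incidence $h_1$ and non-breast-cancer
mortality $h_2$ per person-year. Within a band the two-state survival
process has a closed-form solution, so the projector sums exact per-band
contributions

$$AR = \sum_k S_k\,\frac{r h^*_{1k}}{r h^*_{1k}+h_{2k}}
  \left(1-e^{-(r h^*_{1k}+h_{2k})L_k}\right),
  \qquad S_k=\prod_{j<k} e^{-(r h^*_{1j}+h_{2j})L_j},$$

with no quadrature. This is exact for banded tables (band-splitting
invariance is tested to $10^{-12}$) and agrees with an independent
stiff-ODE integration of the same process to a relative error below
$10^{-8}$ on randomized tables. A band with zero total hazard contributes
zero; ages outside table coverage and $r \le 0$ are rejected rather than
extrapolated.

The packaged rate tables (5-year bands, ages 20–90) are labelled `White`
and `Chinese` and are *synthetic*: they carry the magnitude and age-shape
of US White and urban Chinese female breast-cancer incidence and all-cause
non-breast mortality, but are not transcriptions of any registry. Any table
with the same columns can be substituted, at any banding. Because the
packaged tables extend to age 90, five-year projections are fully covered
for every valid starting age (30–80); we deliberately did not truncate the
horizon at the 80-year eligibility edge, and tables supplied by users must
likewise cover the projection window or the projector refuses.

## The Gail engine

The parsimonious Gail model (model 2) uses five covariates: age at
menarche, age at first live birth, number of first-degree relatives with
breast cancer, number of breast biopsies, and atypical hyperplasia. The
log relative risk is linear in the category codes with two interactions —
biopsies × age regime (\<50 / ≥50 years) and first birth × family history —
plus a hyperplasia multiplier (0.93 / 1.82 / 1.0 for no / yes / unknown)
applied only when at least one biopsy was taken. The coefficients are not
re-estimated here; they ship as a versioned, checksummed JSON fixture
transcribed from the published model, with the category coding documented
in the fixture itself, and user-supplied tables of the same shape are
accepted. The attributable-risk complements $1-AR$ (two age regimes) live
in the rate-table rows, since they convert the composite population
incidence into the baseline incidence the relative risk multiplies.

Missing data follow two explicit policies rather than imputation (the
dominant covariate, biopsies, is almost entirely missing in consortium
data, so model-based imputation would reflect assumptions, not data):

* `baseline` (primary): every unknown is recoded to the
  lowest-relative-risk category, so an all-unknown subject has $r = 1$;
* `highest_risk` (sensitivity): unknowns go to the highest-risk category.
  For age at first birth the "highest" category is resolved as the argmax
  of the packaged main-effect coefficients with ties going to the
  later-listed category (giving `ge30` for the shipped table), because the
  nulliparous and late-first-birth categories can tie under other tables.

The hyperplasia flag is not recoded by either policy: its `unknown` level
already carries a no-effect multiplier of 1, which *is* the baseline
convention for that variable.

Cohort preparation mirrors the upstream analysis: subjects outside ages
30–80 (the Gail validity window) or with unknown age are excluded, and any
(study × disease-status) cell in which at least two of the three core
factors (menarche, first birth, family history) are ≥50% unknown is dropped
— the boundary counts, and the fractions are computed over declared
`unknown` levels only (a structurally absent column is a parse error, not
missingness; the distinction is logged).

## The PRS engine

Raw scores are effect-allele dosage sums, $s_j=\sum_i w_i d_{ij}$, with
per-variant mean imputation of missing dosages (the mean observed dosage,
i.e. twice the dataset allele frequency — the behaviour of standard
sum-score genotype tools). Dosage rows whose alleles are swapped relative
to the weight file are flipped ($d \mapsto 2-d$); a non-swap allele
mismatch is an error; strand-ambiguous A/T and C/G variants are counted and
kept by default (droppable by option) since dosage data carry no strand
cue.

Standardization is against ancestry-specific *control* means and SDs — the
score scale is defined by the unaffected population — and the percentile
is the standard normal CDF of $z$ (the distributional convention implied by
converting standardized scores with the normal CDF; empirical-rank
percentiles are available as an option). Each ancestry is standardized
separately; a per-study option was considered and rejected as the default
because control counts per study can be very small.

The conversion to relative risk uses the theoretical OR of percentile $z$
against the 40–60th percentile band taken to represent the general
population:

$$r(z) = \frac{e^{\beta z}}{c},\qquad
  c = \frac{1}{0.2}\int_{\Phi^{-1}(0.4)}^{\Phi^{-1}(0.6)}
      e^{\beta u}\varphi(u)\,du
    = e^{\beta^2/2}\,
      \frac{\Phi(\Phi^{-1}(0.6)-\beta)-\Phi(\Phi^{-1}(0.4)-\beta)}{0.2},$$

closed-form via the Gaussian tilt identity and verified against adaptive
quadrature to $10^{-10}$. The per-SD log OR $\beta$ is a configuration
parameter; the default $\ln 1.61$ transcribes the per-SD odds ratio
reported for the 313-variant breast cancer PRS in its development
publication.

**Baseline convention.** Two readings of "absolute risk from the
theoretical OR" are defensible: treat the middle band as carrying the raw
population incidence, or rescale the incidence so the *population-average*
risk is conserved. We default to the population-mean constraint — the
incidence hazard is divided by $m = E[r(Z)] = e^{\beta^2/2}/c$ — because it
keeps the cohort-average incidence equal to the rate table's, matching the
established PRS absolute-risk methodology; the mid-quintile alternative is
selectable (`baseline = "mid-quintile"`). Note the constraint conserves the
incidence *hazard*; the mean five-year *risk* matches the $r=1$ projection
only up to a small Jensen gap (about 0.4% relative at 2% risk), which is
why the conservation test uses a 1% relative band. No attributable-risk
adjustment applies to the PRS engine — its baseline is fully handled by
this constraint.

## Evaluation

ORs come from maximum-likelihood logistic regression with Wald 95%
intervals (the convention for large consortium analyses; likelihood-ratio
intervals would be a trivial extension but are not the default). The OR
scale for a continuous five-year risk is ambiguous in common reporting; we
default to *per percentage point* of absolute risk and expose `per-sd` and
`raw` scalings so either convention is reproducible. Perfect separation
and rank deficiency are flagged in the result rather than silently
reported as coefficients. AUCs use the rank (Mann–Whitney) estimator with
ties counted one half and DeLong variance for the interval — `compute_auc`
wraps pROC and is verified against a brute-force pairwise oracle; a
constant score vector returns AUC 0.5 with a degeneracy flag by convention.
Age interaction is the Wald test of the product term in
`status ~ score + age + score:age`, age continuous.

The driver analysis enumerates all $2^5-1 = 31$ non-empty subsets of the
Gail factors, recodes the complement of each subset to missing (hence
baseline), recomputes the five-year risk and reports the stratum AUC. Since
the predictor is the absolute risk, a subset that is 100% missing in a
stratum does not yield a mathematically constant predictor — age still
moves the risk — so such subsets collapse to the identical age-only risk
profile rather than to AUC exactly 0.5; the constant-score convention
applies only when the scores are genuinely constant.

## Overlap and enrichment

High-risk flags are boundary-inclusive ($AR5 \ge t$) so that a quoted
threshold such as 1.4% flags subjects at exactly that risk; the family
history flag is binary (≥1 first-degree relative; unknown counts as no
history, consistent with the baseline recode). The default grid sweeps
0.5%–2.5% in 0.1-point steps, the granularity at which such thresholds are
quoted. The enrichment ratio at threshold $t$ is the flagged *fraction* of
cases divided by the flagged fraction of controls; the raw flagged-count
ratio (the composition of the flagged set) is available behind
`definition = "flagged-count"` because the verbal phrase "twice as many
cases as controls" admits both readings. A threshold flagging zero controls
reports `+Inf` with its counts retained; the minimal-threshold search
treats such a point as reaching any finite target provided at least one
case is flagged.

## Calibration via the model-based ROC

In a case-control sample the event rate does not estimate population
prevalence, so Hosmer–Lemeshow-style absolute calibration tests are not
applicable without design adjustment. The model-based ROC sidesteps this:
given predicted risks $\pi_i$, the curve the model *would* achieve if
perfectly calibrated has, at cut $c$,

$$TPR(c)=\frac{\sum_{\pi_i\ge c}\pi_i}{\sum_i\pi_i},\qquad
  FPR(c)=\frac{\sum_{\pi_i\ge c}(1-\pi_i)}{\sum_i(1-\pi_i)}.$$

Divergence between this curve and the empirical ROC indicates
miscalibration relative to the sample's case mix; predicted risks must be
re-based before population-level claims. Three tests are reported:

* **mean calibration** — $T=(\sum y_i-\sum\pi_i)/\sqrt{\sum\pi_i(1-\pi_i)}$
  against a standard normal (exact Bernoulli-sum variance);
* **ROC equality** — the supremum vertical distance between the empirical
  and model-based curves, with a parametric-bootstrap null that regenerates
  outcomes as independent Bernoulli($\pi_i$) (the resampling scheme is a
  design choice here — it matches the logic of the model-based construction
  and is fully reproducible from the recorded seed);
* **unified** — a min-p combination of the two component statistics,
  calibrated against the same bootstrap draws.

The sup-distance statistic is evaluated on the model curve's FPR
breakpoints (and their left limits), identically for the observed data and
every bootstrap draw; with one breakpoint per distinct risk value this grid
is as fine as the data allow. Monte-Carlo checks in the test suite show all
three tests holding their nominal 5% level (500 replicates at $n=5000$,
200 bootstrap resamples) and the mean-calibration test rejecting a 0.5×
risk-scale distortion essentially always at the same size. Decile
calibration tables (equal-size groups by rank, exact binomial intervals)
are provided for plotting; a constant prediction vector is flagged as a
single effective group.

## The synthetic cohort generator

The generator emulates the case-control structure the analysis assumes,
with defaults transcribed into a versioned fixture
(`inst/extdata/cohort_defaults_table1.json`) describing six
(ancestry × status) cells: sample sizes (68,540 / 83,685 / 9,624 European
controls / invasive / DCIS; 8,347 / 9,222 / 980 Asian), age medians and
quartiles (ages are integer truncated normals matched to median and IQR,
clipped to 30–80), covariate category counts *including the unknown level*
(so realistic missingness — e.g. biopsies ~94–100% unknown — arises by
construction), and raw-PRS location/scale. The case-control PRS shift uses
the liability-logit approximation: controls $z\sim N(0,1)$, cases
$z\sim N(\beta,1)$, so the retrospective logistic slope per true SD is
exactly $\beta$ and the expected case-control AUC is
$\Phi(\beta/\sqrt2)$ — both used as closed-form test targets. Family
history can instead be tilted by an odds ratio against the control-cell
probabilities (`fh_or`), which produces an exact odds-scale enrichment.
Extra missingness is available as MCAR (everyone) or case-only
(MNAR-by-status), the latter to exercise the direction of the
missing-data sensitivity analysis. Controls are labelled population-based
with probability 0.75 by default — the field is needed for the
population-control sensitivity subset and no canonical fraction exists, so
this is a package choice, configurable.

Dosage panels for scoring tests draw Hardy–Weinberg genotypes at
configurable allele frequencies and append two continuous-dosage
adjustment variants (`ADJ_POS`/`ADJ_NEG`, clearly synthetic) whose weighted
contribution absorbs each subject's residual so the panel's weighted sum
reproduces the assigned raw PRS exactly at zero missingness. The
miscalibration generator (`none` / `scale` / `shift`) drives the
calibration-test power checks.

What the generator does **not** emulate: linkage disequilibrium, study-level
heterogeneity (each ancestry is one synthetic "study"), country-level PRS
distribution shifts, covariate-risk correlations beyond those induced by
the cell structure, and any dependence of Gail covariates on case status
beyond the transcribed per-cell prevalences. Passing tests therefore
demonstrate that the machinery is correct and well-calibrated under the
stated data model, not that any particular real cohort satisfies that
model.

## Problem sizes and numerical conventions

The test suite and acceptance script choose sizes that make Monte-Carlo
bands decisive while keeping runs short: 100 randomized rate tables for the
ODE cross-check, $10^5$ draws for uniformity/convergence checks, 1000
replicates at $n\approx5000$ for CI coverage and interaction type-I error,
500 replicates for calibration level/power, and full fixture cell sizes
(180,398 subjects) for the acceptance run, which completes in well under a
minute. Other conventions: thresholds are compared inclusively; threshold
grids are rounded to 10 decimals to avoid floating-point stepping
artifacts; `filter` operations log exact removal counts so
$|input| = |output| + \sum removals$ holds; generators and bootstrap tests
take explicit integer seeds and restore the caller's RNG state.

## Known limitations

The packaged rate tables are synthetic stand-ins: absolute-risk *levels*
(e.g. control medians) are representative rather than registry-exact, so
quantities that depend on the interplay of risk level and threshold (such
as minimal enrichment thresholds) differ from what registry tables would
give, even though all machinery above them is exact. The Gail coefficient
fixture is a transcription, deliberately decoupled from code; users
validating against an external implementation should supply that
implementation's rate and coefficient tables. DCIS analyses reuse the
invasive control pool by design. No survival modelling, lifetime risk,
meta-analysis across studies, or recalibration fitting is included.
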