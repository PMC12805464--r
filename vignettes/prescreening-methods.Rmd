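---
title: "Methods: biomarker rule-out pre-screening evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker rule-out pre-screening evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptauscreen)
```

## The problem and the model

A continuous plasma biomarker Y (pTau217, pg/mL) is evaluated as a
*rule-out* pre-screen for a binary disease state D (amyloid pathology,
referenced by amyloid PET visual read or by a Centiloid threshold). The
screening rule is one-sided: a subject with Y < c is ruled out; a subject
with Y ≥ c proceeds to the confirmatory PET scan. Ties at the cutoff screen
in, so that "below c rules out" holds literally.

Throughout, s and p denote sensitivity P(Y ≥ c | D+) and specificity
P(Y < c | D−) estimated from counts, and π a *specified* prevalence of
amyloid positivity in the population where the screen will be deployed. The
distinction matters: the study sample's case fraction can be distorted by
recruitment (e.g. screen-failure availability), so predictive values are
reported in Bayes form at the deployment prevalence,

$$
\mathrm{PPV} = \frac{s\pi}{s\pi + (1-p)(1-\pi)}, \qquad
\mathrm{NPV} = \frac{p(1-\pi)}{p(1-\pi) + (1-s)\pi}.
$$

Three screening-economics quantities follow. The screen-out rate
$(1-s)\pi + p(1-\pi)$ is the fraction of referrals ruled out. Because the
pre-screen discards a fraction $1-s$ of true positives, enrolling a fixed
number of cases requires pre-screening $1/s$ times as many referrals —
"additional screening required" is $1/s - 1$. Scans are performed only on
screen-ins, so the expected scans per enrolled case shrink by

$$
\text{scans saved} \;=\; 1 - \frac{1 - \text{screen-out}}{s}
\;=\; 1 - (1 + \text{additional screening})(1 - \text{screen-out}),
$$

an algebraic identity the test suite checks to $10^{-12}$. `trial_plan()`
applies these to a target enrollment N: without the pre-screen the expected
number of scans is $N/\pi$; with it, $N/(\pi s)$ referrals are pre-screened
and $N/(\pi s)\,(1-\text{screen-out})$ scanned. One convention choice:
overall percent agreement (OPA) is reported from raw counts, not in
prevalence-adjusted form — the adjusted variant $s\pi + p(1-\pi)$ is also
computed (`opa_adjusted`) but the default report column is the raw count
ratio, which is what the source tables print. Likewise the screen-out rate
is reported in adjusted form rather than as the raw ruled-out fraction;
with π equal to the sample case fraction the two coincide.

## Predictiveness curves and prevalence re-weighting

The integrated-risk display works on the biomarker's percentile scale. For
percentile v, the curve reports the predictiveness R(v) = P(D+ | Y at
quantile v) together with PPV(v) = P(D+ | Y above the v-quantile) and
1−NPV(v) = P(D+ | Y at or below it). The percentile grid has one point per
distinct observed value (ties share a grid point), plus the 0 endpoint;
this keeps the cutoff ↔ percentile mapping invertible: the percentile of a
cutoff c is the fraction of subjects with Y < c, which is exactly the
(adjusted) screen-out rate at c.

Prevalence adjustment is implemented as case/control importance
re-weighting: cases receive weight $\pi/\hat\pi$ and controls
$(1-\pi)/(1-\hat\pi)$, where $\hat\pi$ is the sample case fraction. The
weighted conditional frequencies above/below a grid point then reproduce
the Bayes-form PPV/NPV at the corresponding cutoff *exactly* — the
cross-module identity tests assert agreement to $10^{-12}$, and the mixture
identity $v\,(1{-}\mathrm{NPV})(v) + (1-v)\,\mathrm{PPV}(v) = \pi$ holds at
every interior grid point by construction.

Two estimators are provided:

* **empirical** — re-weighted raw frequencies. With continuous data the
  pointwise risk at a single observation is 0/1-valued; the cumulative
  PPV / 1−NPV series are the informative part of this estimator.
* **monotone** — the risk is constrained to be non-decreasing in Y, which
  is the scientifically meaningful content of a smoothed predictiveness
  fit: biologically, higher pTau217 should not mean lower amyloid risk.
  The estimator is weighted isotonic regression of case status on
  biomarker rank, computed by pool-adjacent-violators (PAVA). A
  constrained additive-model smoother would differ only through its basis
  and penalty, which are free choices; isotonic regression is the
  assumption-minimal member of that family and is the package's deliberate
  stand-in. PAVA preserves the weighted mean, so the fitted curve's
  average risk equals π exactly, and the curve-level PPV/1−NPV are
  averages of fitted risk above/below each grid point.

Grid endpoints use NA for conditioning sets that are empty (1−NPV at
percentile 0, PPV at percentile 1) rather than an arbitrary value.

## ROC inference

The AUC estimator is the midrank Mann–Whitney statistic
$P(Y_+ > Y_-) + \tfrac12 P(Y_+ = Y_-)$, computed from rank sums; it equals
the trapezoidal area under the empirical ROC curve and is invariant under
strictly increasing transforms. Confidence intervals use the DeLong
structural-components variance $S_{10}/n_+ + S_{01}/n_-$ with a normal
approximation, clipped to [0, 1]; the components are computed from ranks
(O(n log n)) and the tests verify them against an explicit double-loop
pair-counting oracle and against `pROC`'s implementation. Perfect
separation gives a zero variance estimate; the interval degenerates to
[auc, auc] with a warning flag rather than an error, since the point
estimate remains meaningful. A stratified bootstrap percentile interval
(`auc_boot_ci()`) is provided as a cross-check utility, not the default.

Pooled ("combined") AUCs concatenate subjects across cohorts rather than
meta-analytically averaging per-cohort estimates. The choice is exposed in
`auc_forest()` only through its `pooled_label` row, and a user preferring
weighted averaging can compute it from the per-cohort rows.

## The synthetic cohort generator

No subject-level data are publicly available, so the generator emulates
the statistical structure the analysis assumes, calibrated to published
stratum summaries:

| stratum | mean (pg/mL) | SD (pg/mL) | n |
|---|---|---|---|
| CI, amyloid+ | 0.835 | 0.381 | 394 |
| CI, amyloid− | 0.361 | 0.294 | 144 |
| CU, amyloid+ | 0.516 | 0.235 | 224 |
| CU, amyloid− | 0.220 | 0.157 | 1386 |

These sizes imply visual-read prevalences of 73.2% (CI) and 13.9% (CU).
Concentrations are positive and right-skewed (median < mean in every
published stratum), so each stratum is modelled as a lognormal
moment-matched to its mean/SD: $\sigma^2 = \log(1 + (sd/m)^2)$,
$\mu = \log m - \sigma^2/2$ — a closed-form inversion with no free
parameters. Draws are censored at the LLoQ (default 0.0693 pg/mL, the
observed assay floor): values below it are floored and flagged `bloq`,
mirroring how below-LLoQ measurements appear in the real data. Censoring
is applied *after* moment-matched sampling although the published targets
describe already-floored data; at the default calibration the resulting
bias is small (the most-censored stratum, CU amyloid−, has ~7% of draws
floored, shifting its mean by ~0.5% and SD by ~0.7%) and is accepted as an
approximation. Parameter-recovery tests therefore exercise the sampler
with the LLoQ set below the distribution's support; censoring behaviour is
tested separately.

For two moment-matched lognormal strata the generator's ROC area has the
closed form $\Phi\big((\mu_+-\mu_-)/\sqrt{\sigma_+^2+\sigma_-^2}\big)$
(`analytic_auc()`), ≈ 0.884 for the CI calibration and ≈ 0.893 for CU —
deliberately close to the published 0.878 and 0.907, since it is derived
from the same summary statistics, but not a reproduction of them. The
acceptance suite checks that pooled empirical AUCs over 200 simulated
cohorts match this closed form within 3 Monte-Carlo standard errors (the
flooring-induced bias is ~10⁻⁵, far below that resolution).

Randomness is reproducible and local: each stratum draws from its own
sub-stream seeded by `seed + 7919 × (row index)`, so resizing one stratum
does not perturb another's values. What the generator does **not** emulate:
covariate structure (age, sex, APOE ε4 effects on pTau217), between-cohort
and assay-batch heterogeneity, Centiloid values correlated with the visual
read, or measurement error beyond the lognormal spread. Tests passing on
synthetic cohorts therefore validate the *estimators and identities*, not
the assay's real-world operating characteristics.

## Cutoff selection and trial planning

`select_rule_out_cutoff()` searches the midpoints between adjacent
distinct biomarker values pooled across the CI and CU tables and returns
the largest candidate whose adjusted NPV is at least `npv_min` (default
0.90) in *both* strata at their respective prevalences — largest, because
NPV-feasible cutoffs trade off directly against the screen-out rate.
Midpoints rather than observed values avoid the knife-edge of placing a
cutoff exactly on a measurement; with perfectly separated strata the
selected cutoff is the gap midpoint. Infeasibility returns `NA` (a result,
not an error). The default NPV floor of 0.90 reflects the conventional
"NPV > 90%" rule-out requirement.

`trial_plan_sweep()` addresses the planning scenario where the CI:CU
composition of referrals is unknown: for a CI fraction f the mixture
prevalence is $f\pi_{CI} + (1-f)\pi_{CU}$ and the mixture sensitivity and
specificity are the case- and control-weighted averages of the stratum
values. The sweep brackets the pure-population endpoints; with the default
parameters the savings are monotone in f (high savings in low-prevalence,
unselected populations; low savings in clinically pre-selected ones).

## Defaults and numerical conventions

* LLoQ 0.0693 pg/mL (observed assay floor); below-LLoQ values are
  substituted at the floor and flagged, so `ptau217 ≥ lloq` after loading.
  How the original analysis treated such values numerically is not
  documented; substitution at the observed minimum reproduces the printed
  data floor and is the package default.
* Rule-out cutoff default 0.189 pg/mL; prevalence defaults 0.6994 for the
  CI stratum (full-cohort adjusted estimate) and the sample case fraction
  for CU (224/1610 ≈ 13.91%). Using the *exact* sample fraction rather
  than its 4-digit rounding is required to reproduce the published CU PPV
  of 23.86% at printed precision.
* Centiloid thresholds 24 and 40 CL, closed lower bounds (≥).
* Confidence level 0.95; percentile bootstrap with stratified resampling
  for the cross-check interval.
* Percentages are rounded half-up to 2 decimals only at the report
  boundary (`run_evaluate()` JSON, acceptance script); all internal values
  keep full precision so rounding never compounds.
* Test problem sizes: moment-matching is verified on 10⁶ Monte-Carlo
  draws, parameter recovery at n = 10⁵ per stratum within 1%, the
  empirical/monotone curve agreement at n = 5×10⁴ with sup-difference
  below 0.02 (on data generated with equal log-scale SDs, hence a
  genuinely monotone true risk), the DeLong-vs-bootstrap agreement with
  20,000 replicates within 0.02, and the closed-form AUC comparison over
  200 simulated cohorts at the published stratum sizes.

## Known limitations

* The monotone estimator is isotonic, i.e. piecewise-constant; it will not
  reproduce the smooth appearance of a spline-based constrained fit, only
  its level sets and all cutoff-level summaries.
* Published real-data AUCs and visual-read/Centiloid concordance rates are
  not reproducible without subject-level data; the package substitutes
  property-based checks (oracle agreement, closed-form calibration) for
  them, and the synthetic Centiloid column is empty by default.
* Bayes-form adjustment assumes sensitivity and specificity transport
  across populations; only the prevalence is re-specified.
* Expected counts in trial planning are expectations, not integers, and
  carry no uncertainty intervals — the source analysis reports point
  estimates only.
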