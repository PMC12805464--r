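# ptauscreen

Screening-performance evaluation for a continuous blood biomarker — plasma
tau phosphorylated at threonine 217 (pTau217) — used as a **rule-out
pre-screen** for amyloid pathology, the hallmark of Alzheimer's disease.
Confirming amyloid status requires an amyloid PET scan (expensive, not
widely available) or a lumbar puncture; a cheap blood test that reliably
*rules out* amyloid-negative individuals before the confirmatory scan can
cut the number of PET scans needed to enroll a trial or triage a memory
clinic. This package is for biostatisticians and trial planners who need to
quantify that trade-off.

## What it computes

Given per-subject records (biomarker value in pg/mL, binary amyloid
reference from a PET visual read or a Centiloid threshold), against a
rule-out convention where values **< cutoff** are screened out and values
**≥ cutoff** go on to PET:

* **ROC/AUC inference** — midrank Mann–Whitney AUC with DeLong
  structural-components confidence intervals, per-cohort and pooled forest
  tables (`auc_empirical()`, `auc_delong()`, `auc_forest()`), and a
  stratified-bootstrap cross-check (`auc_boot_ci()`).
* **Predictiveness (integrated-risk) curves** — risk R(v) = P(D+ | Y at
  percentile v), PPV(v) = P(D+ | Y above v) and 1−NPV(v) = P(D+ | Y at or
  below v) over all possible cutoffs, with an empirical and a monotone
  (weighted isotonic / pool-adjacent-violators) estimator, re-weighted to
  any specified prevalence (`risk_curve()`, `integrated_risk_data()`).
* **Prevalence-adjusted screening metrics** at a cutoff
  (`screening_summary()`, `adjusted_metrics()`):

  PPV = sπ / (sπ + (1−p)(1−π)),  NPV = p(1−π) / (p(1−π) + (1−s)π),

  screen-out rate (1−s)π + p(1−π), additional screening required 1/s − 1,
  and confirmatory **scans saved** 1 − (1 − screen-out)/s, where s, p, π
  are sensitivity, specificity and the adjustment prevalence.
* **Rule-out cutoff selection** — the largest cutoff whose adjusted NPV
  stays above a floor (default 90%) in both the cognitively impaired (CI)
  and unimpaired (CU) strata (`select_rule_out_cutoff()`), plus the full
  cutoff-grid table (`cutoff_grid()`).
* **Trial planning** — expected pre-screened participants and PET scans
  with/without the pre-screen for a target enrollment, across a sweep of
  CI:CU referral mixtures (`trial_plan()`, `trial_plan_sweep()`).
* **Synthetic cohorts** — per-stratum lognormal biomarker mixtures
  moment-matched to published stratum means/SDs, with lower
  limit-of-quantification (LLoQ) censoring and a closed-form AUC check
  (`generate_cohort()`, `lognormal_params()`, `analytic_auc()`).

Everything takes a data frame first and returns a tibble; `risk_curve()`
objects have `tidy()`, `glance()` and `autoplot()` methods, and
`auc_forest()` / `sens_spec_curves()` results autoplot to the familiar
forest and sensitivity/specificity displays.

## Worked example

```r
library(ptauscreen)

cohort <- generate_cohort(default_strata(), seed = 42)  # 538 CI + 1610 CU
ci <- dplyr::filter(cohort, cognitive_status == "CI")

auc_forest(cohort, by = cognitive_status)
#>   label    n_pos n_neg   auc      se ci_low ci_high level degenerate
#> 1 CI         394   144 0.888 0.0190   0.850   0.925  0.95 FALSE
#> 2 CU         224  1386 0.877 0.0101   0.858   0.897  0.95 FALSE
#> 3 Combined   618  1530 0.926 0.00562  0.915   0.937  0.95 FALSE

sm <- screening_summary(ci, cutoff = 0.189, prevalence = 0.6994)
dplyr::select(sm, sensitivity, specificity, ppv, npv, screen_out, scans_saved)
#>   sensitivity specificity   ppv   npv screen_out scans_saved
#> 1           1       0.278 0.763     1     0.0835      0.0835

trial_plan(750, sm$sensitivity, sm$specificity, sm$prevalence)
#>   n_enroll scans_without prescreened scans_with saved_fraction
#> 1      750         1072.       1072.       983.         0.0835
```

Read this as: in a simulated cognitively impaired cohort (amyloid
prevalence adjusted to 69.94%), the biomarker separates amyloid-positive
from amyloid-negative subjects with AUC ≈ 0.89; ruling out everyone below
0.189 pg/mL keeps essentially all true positives (sensitivity ≈ 1), screens
out ≈ 8% of referrals, and would save ≈ 8% of the ~1072 PET scans needed to
enroll 750 amyloid-positive participants. The same pipeline applied to the
unimpaired stratum, where prevalence is low, saves ≈ 40% of scans.

A command-line wrapper over the same functions (`simulate`, `evaluate`,
`profile`, `plan-trial` subcommands) is in `inst/cli/ptauscreen.R`.

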