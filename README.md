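# homacut

Insulin-resistance screening analytics for pediatric cohorts: HOMA-IR
computation, metabolic-syndrome (MS) classification under a modified
ATP III definition, normative and ROC-optimal HOMA-IR cut-points, and
quintile odds-ratio / prevalence analyses — with a seeded synthetic
cohort generator so the entire pipeline is testable end to end without
access to any study data.

## Who this is for

Epidemiologists and biostatisticians working with school-age cohort
data (one row per child: anthropometry, blood pressure, fasting lipids,
glucose and insulin) who need reproducible, convention-explicit
derivations of:

* **HOMA-IR** — `homa_ir(insulin, glucose)` computes
  `insulin [mU/L] × glucose [mmol/L] / 22.5`.
* **MS status** — three or more of: waist ≥ age-sex 90th percentile,
  SBP and/or DBP ≥ age-sex-height 95th percentile, TG ≥ 1.24 mmol/L,
  HDL-C ≤ 1.03 mmol/L, fasting glucose ≥ 5.6 mmol/L. The percentile
  thresholds are derived from the cohort itself
  (`derive_component_thresholds()`), the fixed cuts applied verbatim.
* **Normative cut-offs** — the 95th percentile of HOMA-IR in a healthy
  reference population (normal-weight, zero MS components), stratified
  by sex, age and Tanner stage (`derive_reference_p95_table()`).
* **Discriminative cut-offs** — ROC optima of HOMA-IR against MS by the
  Youden index `J = sens + spec − 1` (maximised) or the squared distance
  to (0,1), `(1−sens)² + (1−spec)²` (minimised), with deterministic tie
  handling (`build_roc()`, `optimal_cutoff()`).
* **Risk gradients** — per-quintile odds ratios of MS and each component
  from ML logistic fits adjusted for age, sex and Tanner stage
  (`assign_quintiles()`, `fit_logistic_or()`), and prevalence-of-IR
  tables across weight-status groups (`prevalence_of_ir()`).

Every percentile in the package uses one quantile convention: linear
interpolation at rank `1 + (n−1)p`.

## Worked example

```r
library(homacut)

report <- run_pipeline(run_config(
  generator = cohort_config(seed = 42, n_subjects = 3200)
))
#> cohort: 3200 subjects
#> metabolic syndrome: 406 of 3200 subjects (12.7%)
#> reference population: 1874 subjects

report
#> <pipeline_report>
#>   subjects: 3200  MS: 406 (12.7%)  reference: 1874
#>   HOMA-IR quintile bounds: 0.611, 0.963, 1.42, 2.33
#>   total-cohort AUC: 0.826
```

The reference table gives the normative cut-offs — note the pubertal
rise (Tanner ≥II p95 = 3.15 vs Tanner I 2.32) that makes a single
threshold inappropriate across ages:

```r
subset(report$reference_table, stratum %in% c("total", "tanner I", "tanner >=II"))
#>       stratum    n  mean    sd  p95
#>         total 1874 1.169 0.881 2.86
#>      tanner I  710 0.983 0.693 2.32
#>   tanner >=II 1164 1.282 0.962 3.15
```

ROC-optimal cut-points sit lower than the normative p95 and trade the
other way (higher sensitivity, lower specificity), as a screening
threshold should:

```r
report$roc_results[, c("stratum", "method", "cutoff", "sensitivity",
                       "specificity", "youden", "auc")]
#>       stratum   method cutoff sensitivity specificity youden   auc
#>         total   youden   1.68       0.766       0.744  0.510 0.826
#>         total      p95   2.86       0.446       0.918  0.364 0.826
#>      tanner I   youden   1.49       0.776       0.750  0.527 0.826
#>      tanner I      p95   2.32       0.534       0.892  0.427 0.826
#>   tanner >=II   youden   2.01       0.743       0.780  0.523 0.831
#>   tanner >=II      p95   3.15       0.433       0.924  0.356 0.831
```

And the risk gradient across HOMA-IR quintiles (quintile 1 referent,
adjusted for age, sex, Tanner stage) is steeply monotone — children in
the top fifth of HOMA-IR have ~50-fold odds of MS:

```r
subset(report$quintile_or, outcome == "MS")[, c("quintile", "n", "n_cases",
                                                "or", "ci_low", "ci_high")]
#>   quintile   n n_cases    or ci_low ci_high
#>          1 640       8  1.00     NA      NA
#>          2 640      19  2.47   1.07    5.68
#>          3 640      44  6.01   2.80   12.89
#>          4 640      88 13.02   6.25   27.12
#>          5 640     247 52.72  25.74  108.01
```

Real cohorts enter through `read_cohort_csv()` (fixed header `id, sex,
age, tanner, height_cm, weight_kg, bmi, wc_cm, fat_pct, sbp, dbp, tc,
tg, hdl, ldl, glucose, insulin`); `run_config(input = "cohort.csv")`
runs the identical pipeline on a file. Generator settings load from
YAML/JSON via `read_cohort_config()`. See
`vignettes/homa-ir-cutoffs.Rmd` for the model, the generator's
assumptions and every numerical convention.

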