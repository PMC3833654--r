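---
title: "Deriving pediatric HOMA-IR cut-points: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving pediatric HOMA-IR cut-points: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(homacut)
library(dplyr)
```

## The problem

Insulin resistance in children is rarely measured directly: the
euglycemic clamp is invasive and expensive, so epidemiological work uses
the homeostasis model assessment,

$$\mathrm{HOMA\text{-}IR} \;=\;
  \frac{\text{fasting insulin } [\mathrm{mU/L}] \times
        \text{fasting glucose } [\mathrm{mmol/L}]}{22.5},$$

a unitless surrogate that correlates well with clamp measures in youths.
The difficulty is the cut-point. Insulin sensitivity falls transiently
during puberty, so a single threshold over ages 6-18 misclassifies both
ends of the pubertal transition, and there is no longitudinal outcome
evidence in children from which to anchor a threshold directly.
`homacut` implements the two standard resolutions side by side:

1. **Normative**: the 95th percentile of HOMA-IR in a *healthy reference
   population* (normal-weight children carrying none of the metabolic
   syndrome components), stratified by sex, age band and Tanner stage.
2. **Discriminative**: the ROC-optimal cut-point of HOMA-IR against
   metabolic syndrome (MS) status, selected by the Youden index
   $J = \mathrm{sens} + \mathrm{spec} - 1$ (maximised) or by the squared
   distance to the ideal corner of the ROC plane,
   $(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2$ (minimised).

MS itself is classified by a modified ATP III pediatric definition:
three or more of (i) waist circumference at or above the cohort's
age-sex 90th percentile, (ii) systolic and/or diastolic blood pressure
at or above the age-sex-height 95th percentile, (iii) triglycerides
$\ge$ 1.24 mmol/L, (iv) HDL-C $\le$ 1.03 mmol/L, (v) fasting glucose
$\ge$ 5.6 mmol/L. The first two thresholds are percentile-derived from
the analysis cohort itself; the last three are fixed cuts, and all five
comparisons are inclusive exactly as written.

## One quantile convention everywhere

Every percentile in the package - waist p90, blood-pressure p95,
growth-reference bands, reference p95, quintile bounds - is computed by
`pct()`: linear interpolation of the order statistics at rank
$h = 1 + (n-1)p$ (the type-7 default of `stats::quantile()`). Published
analyses rarely state their convention; fixing a single ubiquitous one
makes every threshold in a report reproducible from the data and
mutually consistent. Applying a derived p95 back to its own sample
leaves almost exactly 5% strictly above it, which is the package's
self-consistency test.

## The synthetic cohort generator

No subject-level data accompany analyses of this kind, so the package
carries a seeded generator (`generate_cohort()`) whose default
configuration emulates the statistical shape of a mixed school-age
screening cohort of about 3,200 children:

* **Demographics.** Sex Bernoulli (52.4% male), age uniform on 6-18 y,
  Tanner stage drawn from a per-age probability table (stage I dominant
  below 10 y, II-IV over 10-15 y, V from 16 y) - the joint age-puberty
  distribution is otherwise unidentifiable from published tables.
* **A single latent factor.** One standard-normal factor $Z$ per child
  represents the adiposity / insulin-resistance axis; BMI, waist,
  body-fat, both blood pressures, log-triglycerides, HDL-C, glucose and
  log-insulin all load on it. This is what makes the five MS components
  cluster within children, and it is the only dependence mechanism.
* **Insulin** is log-normal with a Tanner-band geometric mean (4.75,
  5.9 and 5.4 mU/L for bands I, II-IV, V by default), times
  $\exp(0.42\,Z + \varepsilon)$, $\varepsilon \sim N(0, 0.59^2)$, so the
  marginal geometric mean per band equals the configured value exactly
  in expectation. The pubertal hump and partial recovery at stage V are
  the reason the normative cut-off must be puberty-stratified.
* **Glucose** is normal (mean 5.08, SD 0.34 mmol/L) with a small
  positive $Z$ loading, floored at 2.5 mmol/L.
* **Height** follows smoothed East-Asian age-sex growth curves with
  5.5 cm residual SD, and weight is back-computed from generated BMI so
  that $\mathrm{BMI} = \mathrm{weight}/\mathrm{height}^2$ holds exactly.

The defaults were calibrated once, by simulation, to sit at: MS
prevalence near 13% (a risk-enriched screening sample, not a general
population), a reference-population HOMA-IR p95 near 3.0 overall and
lower before puberty (about 2.5) than during it (about 3.1), reference
stratum means near 1.0 / 1.3 / 1.2-1.3 for Tanner I / II-IV / V, and
total-cohort ROC discrimination of HOMA-IR against MS near AUC 0.82.
The last anchor fixes the split of insulin's log-scale variance between
the latent loading and the residual (0.42 vs 0.59): the same marginal
with a larger loading produces near-perfect separation of the lowest
HOMA-IR quintile (infinite odds ratios), which real cohorts do not show.

What the generator does **not** emulate: measurement error and assay
non-standardisation, school-level clustering, secular trends, non-linear
age effects, the deliberate oversampling design of screening studies, or
any ethnicity-specific growth reference. A passing test suite therefore
demonstrates that the *pipeline* is correct and that its qualitative
conclusions (monotone risk gradients, puberty-dependent thresholds)
follow from the assumed structure - not that the numerical thresholds
transfer to any real population.

## Cohort-derived component thresholds

`derive_component_thresholds()` uses one-year age bands by default
(configurable), and within-stratum height *tertiles* for the
blood-pressure p95 (configurable count; 1 disables). Published
definitions say "for age, sex and height" without a method; tertile
banding is the documented choice here, and a height-regression variant
was deliberately left out of scope. Every (age band, sex) stratum must
hold at least 20 subjects or derivation aborts naming the stratum -
percentiles from smaller strata would be noise. Thresholds serialise to
JSON (`write_thresholds_json()`) so cut-offs derived on one cohort can
be applied verbatim to another.

Weight status uses an injected growth reference - either percentile
columns (p05/p85/p95) or LMS parameters - because national growth
charts are external data; the test suite builds its reference from the
generator itself. Bands are closed on the left as documented: exactly
p85 is still normal, exactly p95 is still overweight. Children below
the 5th percentile are flagged `underweight` rather than silently
labelled normal, and are excluded from the reference population; how
such children were handled in published analyses is never stated, so
this conservative behaviour is a documented package choice.

## ROC construction and cut-point selection

`build_roc()` takes candidate cut-offs at every distinct observed score
plus one sentinel below the minimum, calling a subject positive when
`score > cutoff` (strictly greater, matching the "HOMA-IR > 3.0"
convention of screening reports; `rule = ">="` is available). With this
candidate set the trapezoidal AUC equals the tie-corrected
Mann-Whitney concordance probability, which the tests verify exactly
against a brute-force pairwise oracle.

`optimal_cutoff()` scans all operating points. Ties on the chosen
criterion are broken by the other criterion and then by the smaller
cut-off, so results are deterministic; published methods are silent on
ties. The distance criterion is minimised on the squared scale exactly
as its bracketed formula is conventionally printed - the square root
changes no argmin. `operating_characteristics()` re-counts sensitivity
and specificity at arbitrary (off-grid) cut-offs, which is how the
normative p95 thresholds are placed on the ROC curve for comparison:
they trade sensitivity for specificity relative to the Youden point, as
expected of a diagnostic rather than screening threshold.

## Quintile odds ratios and prevalence tables

`assign_quintiles()` cuts HOMA-IR at its 20/40/60/80th percentiles
(half-open on the left), with an override for externally published
bounds. `fit_logistic_or()` fits ML logistic regression via `glm`
adjusting for age (continuous), sex, and Tanner stage as a numeric
ordinal (indicator coding behind a flag); quintile 1 is the referent.
Wald 95% intervals are reported, consistent with symmetric-on-log-scale
published intervals. Published work names GEE logistic models but never
a clustering unit, so an independence working model is fitted - point
estimates coincide under independence. Separation or non-convergence is
flagged with unbounded intervals rather than crashing: with strong risk
gradients the lowest quintile can carry very few cases. In the
unadjusted case each quintile OR equals the closed-form $ad/bc$ of the
corresponding 2x2 table, which is both a test oracle
(`crude_or()`, Woolf interval, Haldane-Anscombe 0.5 correction for zero
cells) and a useful sanity check on any fitted table.

`prevalence_of_ir()` reports the percentage of each risk group (MS,
each component, each weight-status class) strictly above each labelled
cut-off, with Pearson chi-squared comparisons (no continuity
correction) across weight-status groups; degenerate tables (a zero
margin, e.g. when every group exceeds a low cut-off) yield flagged `NA`
rows rather than errors.

## Numerical choices and degenerate inputs

* Empty quantile input, single-class ROC labels, an empty reference
  population, undersized threshold strata, missing measurements and
  schema violations are all hard errors naming the offending
  stratum/field; empty *summary* groups (e.g. no child with exactly two
  components) are emitted with `n = 0` and `NA` statistics.
* Quintile grids collapsed by ties are an error, never a silent
  mis-binning.
* Skewed variables (TG, insulin, HOMA-IR) are summarised as geometric
  means (log-scale mean, back-transformed) and flagged `log_scale` in
  `summarize_by_component_count()`.
* Logistic fits run IRLS to a $10^{-10}$ deviance tolerance, 100
  iteration cap.
* Cohort CSVs are written with `%.17g` doubles and parsed with base R's
  strtod-backed converter, so a write/read cycle reproduces every field
  bit for bit.

## Problem sizes in the test suite

The suite exercises cohorts of 1,200-3,200 subjects for end-to-end
patterns (20 seeded replicates for the stochastic ones), 2,000-5,000
for marginal-recovery checks, and instances of at most 50 subjects for
the exact brute-force ROC oracles; the two-class parameter-recovery
simulation uses 1,000 subjects per class with log-normal scores of
equal log-SD 0.5, for which the Youden-optimal threshold is the density
crossing $\exp((\mu_0+\mu_1)/2)$ in closed form. The cut-off estimate
aggregated over 20 replicates recovers that truth well within 0.15;
single-replicate argmaxes fluctuate more (empirical ROC optima converge
at cube-root rate), which is why the check is on the aggregate.

## Known limitations

Thresholds derived here are convention-dependent (quantile type, band
widths, tertile heights) and cohort-dependent; none of them transfer to
a real population without re-derivation. The generator's single-factor
dependence is a deliberate simplification - real component correlations
are not exchangeable through one axis. Confidence intervals for AUC and
cut-points are out of scope, as is the IDF pediatric MS definition and
any multiple-testing adjustment.
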