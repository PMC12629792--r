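---
title: "Models and methods behind ctkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctkinetics)
library(dplyr)
```

## Scope

`ctkinetics` implements a complete exploratory-biomarker workflow for
longitudinal ctDNA monitoring in KRAS-driven tumors: %MAF kinetics and
their coupling to RECIST tumor burden, molecular call rules
(clearance, mResponse, mProgression) with calibrated thresholds,
classical vs. basal-like transcriptomic subtyping with ssGSEA scoring,
and a survival-statistics association engine. A synthetic-cohort
simulator with known generative truth ties the pieces together so the
whole pipeline is testable end to end.

This vignette documents the models, the tunable parameters, the
numerical conventions, and the open design choices — in that order.

## The kinetic model

Tumor burden is summarized by the sum of longest diameters (SLD, mm) of
the RECIST v1.1 target lesions. The working assumption is a
single-phase exponential trajectory per patient,

$$\mathrm{SLD}_i(t) = \mathrm{SLD0}_i \, e^{\rho_i t},$$

with $\rho_i < 0$ for responders and $\rho_i > 0$ for progressors.
ctDNA %MAF is exponentially coupled to burden; on the log10 scale the
relationship is linear:

$$\log_{10} \%\mathrm{MAF}_{ij} = \alpha_i + \beta_i\,\mathrm{SLD}_{ij} + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N(0, \sigma^2).$$

`fit_patient_exponential()` estimates $(\alpha_i, \beta_i)$ by ordinary
least squares on patients with at least three usable points. We adopt
log10 (not natural log) because the coupling is conventionally displayed
on a log10 axis, and unweighted OLS because the measurement-error
structure of digital-PCR %MAF on the log scale is approximately
homoscedastic; neither choice affects $R^2$ and the base only rescales
$\beta$.

The fitted slope converts radiological thresholds into molecular ones.
For a fractional SLD reduction $r$ from baseline $\mathrm{SLD0}_i$:

$$\Delta \%\mathrm{MAF}_i
  = 100\left(1 - 10^{-\beta_i\, r\, \mathrm{SLD0}_i}\right).$$

`translate_sld_threshold()` evaluates this per patient (default $r =
0.30$, the RECIST partial-response bar) and reports the cohort mean and
SD. Under the simulator's default slope and baseline-burden
distributions, the cohort-level translation of a 30% SLD reduction
falls in the low-to-mid 80s of percent %MAF reduction — the regime that
motivates a 90% reduction bar for molecular response.

## Molecular call rules and their parameters

All windows are days from first dose; baselines are the latest
measurement at day ≤ 0 (a first on-treatment value is used, with a
warning, if no pre-dose sample exists).

| Parameter | Default | Meaning |
|---|---|---|
| `mresponse_reduction` | 0.90 | minimum fractional %MAF drop from baseline |
| `mresponse_window_days` | 70 | window for the drop |
| `mprogression_increase` | 0.10 | minimum %MAF rise over a previous value |
| `mprogression_window_days` | 225 | window for the rise |
| `clearance_window_days` | 225 | window for clearance |
| `clearance_threshold` | from data | mean + 3 SD of wild-type %MAF |

Conventions worth making explicit:

* The clearance threshold uses **all** available wild-type
  measurements, not baselines only; with few wild-type patients every
  sample carries information about the assay background, and the
  mean + 3 SD construction is a background bound, not a biological one.
* "10% increase" for mProgression is interpreted **relatively**
  (×1.10 over any previous measurement with a positive value); an
  `absolute_points` mode (10 percentage points) is available behind the
  config switch because the phrasing is genuinely ambiguous.
* Undetected ctDNA is stored as an explicit zero with
  `detected = FALSE` — clearance logic needs the zeros, and log-scale
  fits exclude them unless a positive `pseudo_maf` is supplied (default
  0; the handling of zeros in exponential fits is not standardized, so
  the package makes the choice visible instead of silent).
* Calls are monotone in their thresholds (relaxing
  `mresponse_reduction` can only turn a non-response into a response),
  and re-running any call on the same inputs is bit-identical.

Timepoint pairing matches each SLD assessment to the temporally closest
%MAF measurement; ties resolve to the **earlier** measurement (no
look-ahead), and pairs farther apart than `max_gap_days` (default 21,
roughly a mean sampling offset plus two SDs) are dropped.

Reported percentages (accuracy, sensitivity, specificity) round half
**away** from zero to one decimal, the clinical-reporting convention;
exact values remain available on the evaluation object.

## Survival and screening machinery

Kaplan-Meier curves come from `survival::survfit()` with log-log
(Greenwood) intervals, but the median is defined as the smallest time
with $S(t) \le 0.5$ — the step-function convention — rather than the
midpoint interpolation `survfit` applies when the curve sits exactly at
0.5. The weighted log-rank statistic is implemented directly (weights 1
for the classic test; weight = total number at risk for the
Gehan-Breslow generalized Wilcoxon, which up-weights early differences);
with unit weights it reproduces `survival::survdiff` to 1e-12 in tests.
Gehan-Breslow is hand-built because the `rho` family in `survdiff`
weights by the survival estimate, not by the number at risk. Cox models
use `survival::coxph` with Breslow tie handling (the simplest consistent
default) and Wald intervals; reference levels for categorical covariates
are whatever the supplied factors declare, so "classical" subtype or a
chosen KRAS variant can serve as the comparator.

Fisher's exact test follows the sum-of-probabilities-≤-observed
two-sided convention with the conditional-MLE odds ratio (the
`stats::fisher.test` behavior, cross-checked in tests against full
hypergeometric enumeration). The genomic screen drops features altered
in fewer than three samples before testing and adjusts p-values by
Benjamini-Hochberg within each endpoint family. The confounding screen
routes numeric-numeric pairs to Pearson correlation,
categorical-categorical pairs to Fisher (any expected cell < 5) or
chi-square, and mixed pairs to one-way ANOVA.

A caveat that matters for calibration checks: exact conditional tests
have *discrete, conservative* null distributions —
$P(p \le x) \le x$ with strict inequality at finite counts — so Fisher
p-values are not uniform under the null at any sample size; only the
asymptotic regime approaches uniformity. Continuous-statistic branches
(Pearson, ANOVA) are uniform under the null and are verified as such.

## Subtyping and gene-set scoring

Expression on a variance-stabilized scale is Z-scored per gene
(sample SD, i.e. denominator $n-1$; zero-variance genes dropped with a
warning), the signature genes are projected by PCA, and samples are
partitioned by K-means with $k = 2$ on the first `n_pcs = 2` components.
The dimensionality of the clustering space and the initialization are
genuinely open choices; the package uses 50 random restarts under a
fixed, surfaced seed, which in practice reaches the global best-SSE
partition on small cohorts (verified against exhaustive enumeration for
n ≤ 8). The cluster whose samples have the higher mean Z-score over the
classical signature is labeled "classical" — an explicit convention,
since clustering alone carries no labels. Samples are classified
individually; `collapse_to_patient()` applies a first-biopsy rule when a
patient-level label is needed for survival joins.

ssGSEA follows the rank-weighted ECDF construction: genes are ranked
per sample (ties broken by stable order, with a warning when everything
ties), and the set score is the running sum of the difference between
the in-set ECDF weighted by $\mathrm{rank}^{\alpha}$ ($\alpha = 0.25$)
and the unweighted out-of-set ECDF. Scores are rank-based and hence
invariant to monotone transforms of a sample's expression. Median
stratification is strict: "high" requires a score strictly above the
cohort median, so exact-median values fall to "low".

The published classical/basal-like signature lists are inputs, not
package data: they belong to their original publications and are not
bundled. A clearly labeled synthetic marker GMT ships under
`inst/extdata/` for pipeline exercises, and all correctness tests use
synthetic marker sets.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: a KRAS genotype (defaults
G12D/G12V/G12R/WT ≈ 0.40/0.42/0.11/0.07), a responder flag
(probability 0.42 — a realistic confirmed-response rate for an active
first-line mPDAC regimen), a baseline SLD from LN(log 60, 0.55) mm, a
coupling slope from N(0.058, 0.025) per mm (floored at 0.002), and a
baseline %MAF from LN(log 2, 0.8). The slope and burden distributions
were chosen so the 30%-SLD-to-%MAF translation lands in the ~82 ± 21%
regime described above. Responders shrink at −0.012/day and
non-responders grow at +0.004/day; log10-%MAF noise has SD 0.2 and the
detection floor is 0.005 %MAF. Wild-type patients draw %MAF from a
LN(log 0.01, 0.5) assay background, which puts the derived clearance
threshold near 0.03 %MAF. Survival times are exponential with hazard
multipliers 0.5 (responders) and 1.5 (progressors) on baseline medians
of 450 (OS) and 230 (PFS) days, administratively censored at day 550,
with PFS capped at OS. ctDNA is sampled every 28 days and SLD assessed
every 56 days through day 280; series stop at the radiological
progression assessment (ctDNA 28 days later), as treatment and sampling
stop at progression in practice. Each patient consumes a counter-derived
random substream, so cohorts are byte-identical for identical seeds and
invariant to generation order.

What the generator deliberately does **not** emulate: per-lesion
structure beneath the SLD scalar; irregular visit calendars (the
simulated SLD and ctDNA grids align at 56-day multiples, so pairing gaps
are zero — matching behavior under realistic offsets is exercised by
explicit fixtures in the unit tests instead); stable disease as a
distinct trajectory class (two growth classes only, so best overall
response concentrates on PR and PD); inter-patient correlation;
informative censoring; and sequencing- or droplet-level noise models.
Passing recovery tests on this generator therefore demonstrates the
correctness of the estimators and call rules under the stated model,
not robustness to every feature of real trial data.

A small direct-label generator, `simulate_predictor_labels()`, draws
molecular/radiological label pairs at a chosen prevalence, sensitivity
and specificity; it exists to verify that the confusion-matrix
evaluator recovers a known generative operating point within binomial
error.

## Numerical choices and degenerate inputs

* Zero-margin 2×2 tables: p = 1, odds ratio `NA` (no information).
* TMB exactly at the cohort median classifies as "low" (strict >).
* Microsatellite status: "MSI" at ≥ 20% unstable loci.
* The somatic variant filter excludes any variant with population MAF
  > 0.01 in any reference population and keeps IMPACT MODERATE/HIGH;
  the DNA-damage-repair germline filter (BRCA1/BRCA2/PALB2) keeps
  *common* (MAF ≥ 0.01) HIGH-impact variants — a deliberate,
  documented direction with `strict = FALSE` flipping to the
  conventional rare-variant filter.
* Conflicting tissue/ctDNA KRAS calls return `"conflict"` for manual
  review; they are never silently resolved.
* Shapiro-Wilk is undefined for constant samples; the normality-gated
  comparison treats that case as non-normal and routes to the rank test.
* All clustering entry points take an explicit seed and restart count.

## Problem sizes used in validation

The test-suite recovery experiments use cohorts of 100–500 patients,
100 seeds for subtype recovery, 1,000 replicates for null-calibration
checks, and exhaustive enumeration over all 2×2 tables with total ≤ 30
— sizes at which binomial and KS error bands are tight enough to be
meaningful while the full suite stays fast to run.

## Known limitations

Single-phase exponential trajectories cannot show response followed by
regrowth unless the optional two-phase mode is enabled; the calling
rules assume day-anchored visits and do not model assay batch effects;
the association engine tests marginal associations only (no
multiplicity-aware model selection); and the conservativeness of exact
tests under discreteness (noted above) means null p-value uniformity
should only be expected of the continuous-statistic branches.
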