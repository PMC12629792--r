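# ctkinetics

Longitudinal circulating tumor DNA (ctDNA) analysis for oncology cohorts:
mutant-allele-fraction kinetics coupled to radiological tumor burden,
molecular response / progression / clearance calling, transcriptomic
subtyping, and a feature-by-endpoint association engine — together with a
seeded synthetic-cohort simulator so that every stage can be exercised and
validated without access to patient-level data.

The package is written for translational biostatisticians analyzing trials
in KRAS-driven cancers (the defaults are tuned to metastatic pancreatic
ductal adenocarcinoma, mPDAC), where plasma KRAS G12 mutant fragments are
quantified by digital PCR and tumor burden is assessed by RECIST v1.1.

## The model

The mutant allele fraction, expressed as a percentage, is

```
%MAF = 100 · c_mut / c_tot
```

with `c_mut` and `c_tot` the mutant and total plasma copy concentrations.
%MAF is exponentially coupled to the sum of longest diameters (SLD, mm) of
the RECIST target lesions; per patient *i*,

```
log10(%MAF_ij) = α_i + β_i · SLD_ij + ε_ij,   ε_ij ~ N(0, σ²)
```

so a patient-specific ordinary-least-squares fit of `log10(%MAF)` on SLD
(patients with ≥ 3 usable points) yields the slope `β_i` (per mm) that
converts radiological thresholds into molecular ones: a fractional SLD
reduction `r` translates into a %MAF reduction of
`100·(1 − 10^(−β_i · r · SLD0_i))`.

On top of the kinetics sit the calling rules:

* **ctDNA clearance** — %MAF at or below the wild-type background threshold
  (mean + 3 SD of %MAF in KRAS wild-type patients) within the first 225
  days;
* **molecular response (mResponse)** — ≥ 90% reduction from baseline in
  %MAF within the first 70 days;
* **molecular progression (mProgression)** — ≥ 10% increase over any
  previous measurement within the first 225 days.

Calls are compared against RECIST labels via confusion-matrix metrics and
lead times, and carried into survival analyses (Kaplan-Meier, log-rank and
Gehan-Breslow weighted tests, Cox proportional hazards), Fisher screens of
binary genomic features with Benjamini-Hochberg FDR, ssGSEA gene-set
scoring with median stratification, and classical vs. basal-like subtype
classification (Z-score → PCA → K-means).

## Worked example

```r
library(ctkinetics)
library(dplyr)

co <- simulate_cohort(cohort_config(n_patients = 57, seed = 7))
ctdna <- left_join(co$ctdna, co$patients[, c("patient_id", "genotype")],
                   by = "patient_id")
calls <- call_molecular(ctdna)
glance(calls)
#> # A tibble: 1 × 6
#>   n_patients n_evaluable n_cleared n_mresponse n_mprogression clearance_threshold
#> 1         50          50        17          16             35              0.0301
```

Fifty of the 57 simulated patients carry a detectable KRAS G12 mutation
(the wild-type patients define the clearance threshold, here 0.030 %MAF,
and are excluded from calling); 17 clear their ctDNA, 16 reach a molecular
response and 35 show a molecular progression under the default windows.

```r
joined <- inner_join(tidy(calls), co$patients, by = "patient_id") |>
  filter(evaluable)
evaluate_predictor(joined$mresponse, joined$bor %in% c("CR", "PR"))
#> Predictor evaluation (n = 50)
#>   TP 16  FN 7  FP 0  TN 27
#>   accuracy 86.0%  sensitivity 69.6%  specificity 100.0%
```

Molecular response predicts the confirmed radiological response with 86%
accuracy on this cohort: every mResponse call corresponds to a confirmed
partial response, while seven responders reach the 90% %MAF reduction
only after the 70-day window.

```r
pairs <- pair_cohort(co$sld, co$ctdna)
correlate_maf_sld(pairs)
#> # A tibble: 2 × 4
#>   scale        r        p     n
#> 1 absolute 0.526 1.12e-12   159
#> 2 relative 0.292 1.45e- 5   214
```

The SLD-log10(%MAF) correlation on the absolute scale is r = 0.53 across
159 detected paired measurements, reflecting the generative exponential
coupling blurred by measurement noise and the detection floor.

See the methods vignette (`vignettes/ctdna-kinetics.Rmd`) for the model,
parameter and design discussion.

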