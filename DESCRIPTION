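Package: ctkinetics
Title: Circulating Tumor DNA Kinetics, Molecular Response Calling, and
    Biomarker Association Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal circulating tumor DNA (ctDNA) analysis in
    oncology cohorts: mutant-allele-fraction (%MAF) kinetics and their
    exponential coupling to radiological tumor burden (RECIST sum of longest
    diameters), calling of molecular response, molecular progression, and
    ctDNA clearance with calibrated thresholds, classical versus basal-like
    transcriptomic subtyping (Z-score, PCA, K-means) with single-sample gene
    set enrichment (ssGSEA) scoring, and a feature-by-endpoint association
    engine (Fisher screens, Kaplan-Meier estimates, weighted log-rank and
    Gehan-Breslow tests, Cox proportional hazards models, fold-change and
    normality-gated group comparisons, variant filtering, confounding
    screens). A seeded synthetic-cohort simulator generates patient tables,
    tumor-burden and ctDNA series, expression matrices, immune panels, and
    survival endpoints with known ground truth so every stage is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
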