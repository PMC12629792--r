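#' Pair a whole cohort's tumor-burden and ctDNA series
#'
#' Applies [match_timepoints()] per patient over long tables.
#'
#' @param sld Long tibble: `patient_id`, `day`, `sld_mm`.
#' @param ctdna Long tibble: `patient_id`, `day`, `maf_pct`.
#' @param max_gap_days Maximum pairing gap (default 21).
#' @return Tibble of paired points with `patient_id`.
#' @export
pair_cohort <- function(sld, ctdna, max_gap_days = 21) {
  assert_cols(sld, c("patient_id", "day", "sld_mm"), "sld")
  assert_cols(ctdna, c("patient_id", "day", "maf_pct"), "ctdna")
  ids <- intersect(unique(sld$patient_id), unique(ctdna$patient_id))
  purrr::map_dfr(ids, function(id) {
    p <- suppressWarnings(match_timepoints(
      sld[sld$patient_id == id, c("day", "sld_mm")],
      ctdna[ctdna$patient_id == id, c("day", "maf_pct")],
      max_gap_days
    ))
    if (nrow(p) > 0) dplyr::mutate(p, patient_id = id, .before = 1) else p
  })
}

#' Run the full cohort analysis
#'
#' Orchestrates the analysis stages on a cohort bundle: pair tumor-burden
#' and ctDNA series, fit patient-specific exponential models and correlate
#' %MAF with SLD, call clearance / molecular response / molecular
#' progression, evaluate the molecular calls against RECIST labels with
#' lead times, classify molecular subtypes from the expression matrix, and
#' summarize survival by clearance stratum. Stages whose inputs are absent
#' are skipped and noted in the summary. Deterministic given `seed`.
#'
#' @param cohort A `ct_cohort` bundle (from [simulate_cohort()] or
#'   [load_cohort()]).
#' @param call_config A [molecular_call_config()].
#' @param max_gap_days Pairing gap limit (default 21).
#' @param seed Seed for the (seeded) clustering stages.
#' @param out_dir Optional directory; when given, result tables and
#'   `summary.json` are written there.
#' @return A list of class `ct_analysis`: `pairs`, `fits`, `correlation`,
#'   `calls`, `evaluation`, `subtypes`, `km`, `summary` (the JSON-ready
#'   summary list), `skipped`.
#' @export
run_full_analysis <- function(cohort,
                              call_config = molecular_call_config(),
                              max_gap_days = 21, seed = 1, out_dir = NULL) {
  stopifnot(inherits(cohort, "ct_cohort"))
  res <- list(skipped = character())
  summary <- list()

  has_ctdna <- !is.null(cohort$ctdna) && !is.null(cohort$sld)
  if (has_ctdna) {
    ctdna <- cohort$ctdna
    if (!"genotype" %in% names(ctdna) && !is.null(cohort$patients)) {
      ctdna <- dplyr::left_join(
        ctdna, cohort$patients[, c("patient_id", "genotype")],
        by = "patient_id"
      )
    }
    res$pairs <- pair_cohort(cohort$sld, cohort$ctdna, max_gap_days)
    res$fits <- fit_exponential_models(res$pairs)
    res$correlation <- tryCatch(correlate_maf_sld(res$pairs),
                                error = function(e) NULL)
    res$calls <- call_molecular(ctdna, call_config)

    summary$gaps <- as.list(gap_summary(res$pairs))
    summary$molecular_calls <- as.list(glance(res$calls))

    if (!is.null(cohort$patients) && "bor" %in% names(cohort$patients)) {
      joined <- dplyr::inner_join(
        tidy(res$calls), cohort$patients, by = "patient_id"
      )
      joined <- joined[joined$evaluable %in% TRUE, ]
      if (nrow(joined) > 0) {
        radiological <- joined$bor %in% c("CR", "PR")
        ev <- evaluate_predictor(joined$mresponse, radiological)
        lead <- compute_lead_time(joined$mresponse_day, joined$response_day)
        res$evaluation <- ev
        summary$mresponse_evaluation <- as.list(glance(ev))
        summary$mresponse_lead_time <- as.list(lead_time_summary(lead))
        radiological_pd <- !is.na(joined$progression_day)
        evp <- evaluate_predictor(joined$mprogression %in% TRUE,
                                  radiological_pd)
        res$evaluation_progression <- evp
        summary$mprogression_evaluation <- as.list(glance(evp))
      }
    }
  } else {
    res$skipped <- c(res$skipped, "ctdna_kinetics")
    summary$skipped_stages <- I("ctdna_kinetics")
  }

  if (!is.null(cohort$expression) && !is.null(cohort$gene_sets) &&
      all(c("classical", "basal") %in% names(cohort$gene_sets))) {
    res$subtypes <- classify_molecular_subtype(
      cohort$expression$values,
      cohort$gene_sets$classical, cohort$gene_sets$basal,
      seed = seed
    )
    summary$subtype_counts <- as.list(table(res$subtypes$subtype))
  } else {
    res$skipped <- c(res$skipped, "subtype_scoring")
  }

  if (!is.null(cohort$survival) && !is.null(res$calls)) {
    sv <- dplyr::inner_join(cohort$survival, tidy(res$calls),
                            by = "patient_id")
    sv <- sv[sv$evaluable %in% TRUE & !is.na(sv$cleared), ]
    if (nrow(sv) > 0 && length(unique(sv$cleared)) == 2) {
      km_by <- lapply(split(sv, sv$cleared), function(d) {
        km_estimate(d$os_days, d$os_event)$median
      })
      lr <- weighted_logrank_test(sv$os_days, sv$os_event, sv$cleared)
      res$km <- km_by
      summary$os_median_by_clearance <- km_by
      summary$os_logrank_p <- lr$p
    }
  }

  res$summary <- summary
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$pairs)) {
      readr::write_csv(res$pairs, file.path(out_dir, "pairs.csv"))
    }
    if (!is.null(res$fits)) {
      readr::write_csv(tidy(res$fits), file.path(out_dir, "fits.csv"))
    }
    if (!is.null(res$calls)) {
      readr::write_csv(tidy(res$calls), file.path(out_dir, "calls.csv"))
    }
    if (!is.null(res$subtypes)) {
      readr::write_csv(res$subtypes, file.path(out_dir, "subtypes.csv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(res, class = "ct_analysis")
}
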