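#' Cohort simulation configuration
#'
#' Builds the parameter set for [simulate_cohort()]. Defaults emulate a
#' first-line metastatic pancreatic cancer cohort under an active regimen:
#' lognormal baseline tumor burden around 60 mm, a confirmed response
#' probability of 0.42, single-phase exponential tumor-burden trajectories,
#' and ctDNA %MAF coupled exponentially to tumor burden (linear in
#' log10 space) with lognormal detection noise.
#'
#' @param n_patients Number of patients.
#' @param genotype_probs Named probabilities for KRAS genotypes
#'   `G12D`, `G12V`, `G12R`, `WT`; must sum to 1.
#' @param baseline_sld_meanlog,baseline_sld_sdlog Lognormal parameters for
#'   baseline sum of longest diameters (mm).
#' @param growth_rate_responder Per-day fractional SLD change for responders
#'   (negative: tumor shrinkage).
#' @param growth_rate_progressor Per-day fractional SLD change for
#'   non-responders (positive: growth).
#' @param response_prob Probability a patient is a responder.
#' @param coupling_slope_beta Mean per-mm slope of log10(%MAF) against SLD.
#' @param beta_sd Between-patient standard deviation of the coupling slope.
#' @param baseline_maf_meanlog,baseline_maf_sdlog Lognormal parameters of
#'   the baseline %MAF in KRAS-mutant patients; each patient's intercept is
#'   anchored so that log10(%MAF) at the baseline SLD equals the drawn
#'   baseline %MAF.
#' @param maf_noise_sd Standard deviation of additive noise on log10(%MAF).
#' @param detection_floor_pct %MAF below which a measurement is recorded as 0
#'   (undetected). Must be >= 0.
#' @param wt_maf_meanlog,wt_maf_sdlog Lognormal parameters of the assay
#'   background %MAF measured in KRAS wild-type patients.
#' @param visit_days ctDNA sampling days; strictly increasing, first day 0.
#' @param sld_visit_days Radiological assessment days; strictly increasing,
#'   first day 0.
#' @param two_phase If `TRUE`, responder trajectories regrow after
#'   `switch_day` at rate `abs(growth_rate_progressor)` (exercises molecular
#'   progression after response).
#' @param switch_day Day at which two-phase trajectories switch to regrowth.
#' @param survival_link Named hazard multipliers (`responder`, `progressor`)
#'   applied to the baseline hazards.
#' @param os_hazard,pfs_hazard Baseline daily exponential hazards for overall
#'   and progression-free survival.
#' @param admin_censor_day Administrative censoring day for survival.
#' @param followup_extra_days ctDNA sampling continues this many days past
#'   radiological progression before the series stops (treatment stop).
#' @param seed Integer seed; identical seed and config give byte-identical
#'   cohorts.
#'
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = 57,
                          genotype_probs = c(G12D = 0.40, G12V = 0.42,
                                             G12R = 0.11, WT = 0.07),
                          baseline_sld_meanlog = log(60),
                          baseline_sld_sdlog = 0.55,
                          growth_rate_responder = -0.012,
                          growth_rate_progressor = 0.004,
                          response_prob = 0.42,
                          coupling_slope_beta = 0.058,
                          beta_sd = 0.025,
                          baseline_maf_meanlog = log(2),
                          baseline_maf_sdlog = 0.8,
                          maf_noise_sd = 0.2,
                          detection_floor_pct = 0.005,
                          wt_maf_meanlog = log(0.01),
                          wt_maf_sdlog = 0.5,
                          visit_days = seq(0, 280, by = 28),
                          sld_visit_days = seq(0, 280, by = 56),
                          two_phase = FALSE,
                          switch_day = 140,
                          followup_extra_days = 28,
                          survival_link = c(responder = 0.5, progressor = 1.5),
                          os_hazard = log(2) / 450,
                          pfs_hazard = log(2) / 230,
                          admin_censor_day = 550,
                          seed = 1) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    ck_abort("`n_patients` must be a positive integer.")
  }
  required <- c("G12D", "G12V", "G12R", "WT")
  if (!all(required %in% names(genotype_probs))) {
    ck_abort("`genotype_probs` must name G12D, G12V, G12R and WT.")
  }
  if (any(genotype_probs < 0) || abs(sum(genotype_probs) - 1) > 1e-9) {
    ck_abort("`genotype_probs` must be nonnegative and sum to 1 (within 1e-9).")
  }
  assert_prob(response_prob, "response_prob")
  if (detection_floor_pct < 0) ck_abort("`detection_floor_pct` must be >= 0.")
  if (maf_noise_sd < 0) ck_abort("`maf_noise_sd` must be >= 0.")
  for (vd in list(visit_days, sld_visit_days)) {
    if (length(vd) == 0) ck_abort("visit schedules must be nonempty.")
    if (vd[1] != 0 || any(diff(vd) <= 0)) {
      ck_abort("visit schedules must be strictly increasing and start at day 0.")
    }
  }
  if (any(survival_link <= 0) || os_hazard <= 0 || pfs_hazard <= 0) {
    ck_abort("hazards and hazard multipliers must be positive.")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      genotype_probs = genotype_probs[required],
      baseline_sld_meanlog = baseline_sld_meanlog,
      baseline_sld_sdlog = baseline_sld_sdlog,
      growth_rate_responder = growth_rate_responder,
      growth_rate_progressor = growth_rate_progressor,
      response_prob = response_prob,
      coupling_slope_beta = coupling_slope_beta,
      beta_sd = beta_sd,
      baseline_maf_meanlog = baseline_maf_meanlog,
      baseline_maf_sdlog = baseline_maf_sdlog,
      maf_noise_sd = maf_noise_sd,
      detection_floor_pct = detection_floor_pct,
      wt_maf_meanlog = wt_maf_meanlog,
      wt_maf_sdlog = wt_maf_sdlog,
      visit_days = visit_days,
      sld_visit_days = sld_visit_days,
      two_phase = isTRUE(two_phase),
      switch_day = switch_day,
      followup_extra_days = followup_extra_days,
      survival_link = survival_link,
      os_hazard = os_hazard,
      pfs_hazard = pfs_hazard,
      admin_censor_day = admin_censor_day,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate an exponential tumor-burden trajectory
#'
#' SLD follows `baseline * exp(rate * day)`. In two-phase mode the trajectory
#' decays until `switch_day` and then regrows at `regrowth_rate`.
#'
#' @param baseline_sld Baseline SLD in mm (> 0).
#' @param rate Per-day fractional change (negative = shrinkage).
#' @param visit_days Nonnegative assessment days (first should be 0).
#' @param two_phase Switch to regrowth after `switch_day`?
#' @param switch_day Day of the growth-phase switch.
#' @param regrowth_rate Per-day rate after the switch (used when `two_phase`).
#' @return A tibble with columns `day`, `sld_mm`.
#' @examples
#' simulate_sld_trajectory(50, -0.01, c(0, 30))
#' @export
simulate_sld_trajectory <- function(baseline_sld, rate, visit_days,
                                    two_phase = FALSE, switch_day = 140,
                                    regrowth_rate = 0.004) {
  if (baseline_sld <= 0) ck_abort("`baseline_sld` must be > 0.")
  if (any(visit_days < 0)) ck_abort("`visit_days` must be nonnegative.")
  day <- as.numeric(visit_days)
  if (two_phase) {
    sld <- ifelse(
      day <= switch_day,
      baseline_sld * exp(rate * day),
      baseline_sld * exp(rate * switch_day) *
        exp(regrowth_rate * (day - switch_day))
    )
  } else {
    sld <- baseline_sld * exp(rate * day)
  }
  tibble::tibble(day = day, sld_mm = pmax(sld, 0))
}

#' Simulate ctDNA %MAF from a tumor-burden series
#'
#' %MAF is exponentially coupled to SLD:
#' `maf_pct = 10^(intercept + true_beta * sld_mm + eps)` with
#' `eps ~ N(0, noise_sd)`. Values below `detection_floor` are recorded as 0
#' with `detected = FALSE` (explicit zeros, so clearance logic can use them).
#'
#' @param sld Tibble with columns `day`, `sld_mm` (nonempty).
#' @param true_beta Per-mm slope of log10(%MAF) on SLD.
#' @param intercept Intercept of log10(%MAF).
#' @param noise_sd Standard deviation of the log10-scale noise (>= 0).
#' @param detection_floor %MAF below which the assay reads 0.
#' @param seed Optional integer seed for the noise draws.
#' @return A tibble with columns `day`, `maf_pct`, `detected`.
#' @export
simulate_ctdna_from_sld <- function(sld, true_beta, intercept, noise_sd = 0,
                                    detection_floor = 0, seed = NULL) {
  if (nrow(sld) == 0) ck_abort("`sld` must be nonempty.")
  if (noise_sd < 0) ck_abort("`noise_sd` must be >= 0.")
  draw <- function() {
    if (noise_sd > 0) rnorm(nrow(sld), 0, noise_sd) else numeric(nrow(sld))
  }
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  maf <- 10^(intercept + true_beta * sld$sld_mm + eps)
  detected <- maf >= detection_floor & maf > 0
  tibble::tibble(
    day = sld$day,
    maf_pct = ifelse(detected, maf, 0),
    detected = detected
  )
}

#' Derive RECIST labels from an SLD series
#'
#' Applies RECIST v1.1 target-lesion rules to a longitudinal SLD series:
#' partial response (PR) when SLD drops >= 30% from baseline, complete
#' response (CR) when SLD reaches 0, progressive disease (PD) when SLD rises
#' >= 20% above the nadir of all earlier assessments *and* >= 5 mm in
#' absolute terms. A response is confirmed only if the response-level
#' shrinkage is observed again at least `confirmation_days` later.
#'
#' @param sld Tibble with columns `day`, `sld_mm`; must contain a baseline
#'   measurement at day <= 0.
#' @param confirmation_days Minimum days between the first response-level
#'   assessment and its confirmation (default 28).
#' @return A one-row tibble: `bor` (best overall response, one of
#'   `"CR","PR","SD","PD"`), `response_day` (first day the confirmed response
#'   criterion was met, `NA` if none), `progression_day` (first PD day, `NA`
#'   if none).
#' @export
derive_recist_labels <- function(sld, confirmation_days = 28) {
  sld <- dplyr::arrange(sld, .data$day)
  base_idx <- which(sld$day <= 0)
  if (length(base_idx) == 0) {
    ck_abort("missing baseline: no SLD measurement at day <= 0.",
             class = "ctkinetics_baseline_error")
  }
  baseline <- sld$sld_mm[max(base_idx)]
  on <- dplyr::filter(sld, .data$day > 0)
  if (nrow(on) == 0) {
    return(tibble::tibble(bor = "SD", response_day = NA_real_,
                          progression_day = NA_real_))
  }

  pct_change <- 100 * (on$sld_mm - baseline) / baseline
  resp_level <- pct_change <= -30 | on$sld_mm == 0

  # nadir over baseline and strictly earlier on-treatment assessments
  prior_min <- vapply(seq_len(nrow(on)), function(i) {
    min(c(baseline, on$sld_mm[seq_len(i - 1)]))
  }, numeric(1))
  pd <- on$sld_mm >= 1.2 * prior_min & (on$sld_mm - prior_min) >= 5

  progression_day <- if (any(pd)) on$day[which(pd)[1]] else NA_real_

  # response confirmation: criterion holds again >= confirmation_days later
  response_day <- NA_real_
  confirmed <- FALSE
  first_resp <- which(resp_level)
  for (i in first_resp) {
    later <- which(resp_level & on$day >= on$day[i] + confirmation_days)
    if (length(later) > 0) {
      response_day <- on$day[i]
      confirmed <- TRUE
      break
    }
  }

  cr <- any(on$sld_mm == 0) && confirmed
  bor <- if (confirmed && cr) {
    "CR"
  } else if (confirmed) {
    "PR"
  } else if (!is.na(progression_day) &&
             (!any(resp_level) || progression_day < on$day[first_resp[1]])) {
    "PD"
  } else {
    "SD"
  }
  # unconfirmed response followed by progression counts as PD-free interval
  if (!confirmed && !is.na(progression_day)) bor <- "PD"
  tibble::tibble(bor = bor, response_day = response_day,
                 progression_day = progression_day)
}

#' Simulate a two-subtype expression matrix
#'
#' Background genes are iid Gaussian (variance-stabilized scale); marker
#' genes are shifted by `effect_size` in the samples of their own subtype.
#' With `effect_size = 0` no gene carries label information (null case).
#'
#' @param n_samples Number of samples.
#' @param subtype_labels Character vector (`"classical"`/`"basal-like"`) of
#'   length `n_samples`.
#' @param classical_genes,basal_genes Disjoint marker gene ID vectors.
#' @param effect_size Mean shift (in SD units) of markers in their subtype.
#' @param n_background Number of uninformative background genes.
#' @param scale `"vst"` (Gaussian, default) or `"tpm"` (strictly positive,
#'   `2^x` transformed).
#' @param seed Integer seed.
#' @return A list with `values` (genes x samples matrix), `gene_ids`,
#'   `sample_ids`, `scale`.
#' @export
simulate_expression_matrix <- function(n_samples, subtype_labels,
                                       classical_genes, basal_genes,
                                       effect_size = 3, n_background = 450,
                                       scale = c("vst", "tpm"), seed = 1) {
  scale <- match.arg(scale)
  if (length(intersect(classical_genes, basal_genes)) > 0) {
    ck_abort("classical and basal marker lists must be disjoint.")
  }
  if (length(subtype_labels) != n_samples) {
    ck_abort("`subtype_labels` must have length `n_samples`.")
  }
  genes <- c(classical_genes, basal_genes,
             sprintf("BG%04d", seq_len(n_background)))
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(genes) * n_samples), nrow = length(genes),
                dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    cl <- subtype_labels == "classical"
    m[classical_genes, cl] <- m[classical_genes, cl] + effect_size
    m[basal_genes, !cl] <- m[basal_genes, !cl] + effect_size
    if (scale == "tpm") m <- 2^m
    list(values = m, gene_ids = genes, sample_ids = colnames(m), scale = scale)
  })
}

#' Simulate a longitudinal immune panel
#'
#' Generates a long-format table of immune population frequencies at the
#' dosing-anchored visits C1D1 (baseline, pre-dose), C1D2, C1D8 and C2D1.
#' `effect_map` injects multiplicative post-dose shifts for chosen
#' populations in chosen patient strata.
#'
#' @param patients Tibble with `patient_id` and logical `is_responder`.
#' @param populations Character vector of population names.
#' @param effect_map Optional tibble with columns `population`, `stratum`
#'   (`"responder"`, `"progressor"` or `"all"`) and `fold` (> 0): the
#'   multiplicative shift applied at every post-baseline visit.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline frequency (percent).
#' @param noise_sd Lognormal visit-to-visit noise SD (log scale).
#' @param seed Integer seed.
#' @return Long tibble: `patient_id`, `day_label`, `population`, `frequency`
#'   (percent, in `[0, 100]`).
#' @export
simulate_immune_panel <- function(patients, populations,
                                  effect_map = NULL,
                                  baseline_meanlog = log(5),
                                  baseline_sdlog = 0.5,
                                  noise_sd = 0.1, seed = 1) {
  day_labels <- c("C1D1", "C1D2", "C1D8", "C2D1")
  if (!is.null(effect_map)) {
    assert_cols(effect_map, c("population", "stratum", "fold"), "effect_map")
    if (any(effect_map$fold <= 0)) ck_abort("`fold` must be > 0.")
    if (!all(effect_map$stratum %in% c("responder", "progressor", "all"))) {
      ck_abort("`stratum` must be responder, progressor or all.")
    }
  }
  grid <- tidyr::expand_grid(
    patient_id = patients$patient_id,
    population = populations
  )
  withr::with_seed(seed, {
    grid$baseline <- pmin(
      rlnorm(nrow(grid), baseline_meanlog, baseline_sdlog), 100
    )
    out <- tidyr::expand_grid(grid, day_label = day_labels)
    out <- dplyr::left_join(
      out,
      dplyr::select(patients, "patient_id", "is_responder"),
      by = "patient_id"
    )
    fold <- rep(1, nrow(out))
    if (!is.null(effect_map)) {
      for (i in seq_len(nrow(effect_map))) {
        hit <- out$population == effect_map$population[i] &
          out$day_label != "C1D1" &
          (effect_map$stratum[i] == "all" |
             (effect_map$stratum[i] == "responder" & out$is_responder) |
             (effect_map$stratum[i] == "progressor" & !out$is_responder))
        fold[hit] <- fold[hit] * effect_map$fold[i]
      }
    }
    noise <- ifelse(out$day_label == "C1D1", 0, rnorm(nrow(out), 0, noise_sd))
    out$frequency <- pmin(out$baseline * fold * exp(noise), 100)
    dplyr::select(out, "patient_id", "day_label", "population", "frequency")
  })
}

#' Simulate survival endpoints linked to response status
#'
#' Exponential event times with the baseline hazard multiplied by
#' `survival_link["responder"]` or `survival_link["progressor"]`;
#' administrative censoring at `admin_censor_day`; PFS is capped at OS.
#'
#' @param truth Tibble with `patient_id` and logical `is_responder`.
#' @param survival_link Named positive hazard multipliers.
#' @param os_hazard,pfs_hazard Baseline daily hazards (> 0).
#' @param admin_censor_day Administrative censoring day (>= 0).
#' @param seed Integer seed.
#' @return Tibble: `patient_id`, `os_days`, `os_event`, `pfs_days`,
#'   `pfs_event`.
#' @export
simulate_survival <- function(truth,
                              survival_link = c(responder = 0.5,
                                                progressor = 1.5),
                              os_hazard = log(2) / 450,
                              pfs_hazard = log(2) / 230,
                              admin_censor_day = 550, seed = 1) {
  if (any(survival_link <= 0) || os_hazard <= 0 || pfs_hazard <= 0) {
    ck_abort("hazards and multipliers must be positive.")
  }
  n <- nrow(truth)
  mult <- ifelse(truth$is_responder, survival_link[["responder"]],
                 survival_link[["progressor"]])
  withr::with_seed(seed, {
    os_t <- rexp(n, rate = os_hazard * mult)
    pfs_t <- pmin(rexp(n, rate = pfs_hazard * mult), os_t)
    tibble::tibble(
      patient_id = truth$patient_id,
      os_days = pmin(os_t, admin_censor_day),
      os_event = as.integer(os_t <= admin_censor_day),
      pfs_days = pmin(pfs_t, admin_censor_day),
      pfs_event = as.integer(pfs_t <= admin_censor_day)
    )
  })
}

#' Simulate paired molecular/radiological labels with known operating point
#'
#' Draws a radiological truth label with the given prevalence and a molecular
#' prediction with the given sensitivity and specificity; used to check that
#' predictor evaluation recovers a known generative operating point.
#'
#' @param n Number of patients.
#' @param prevalence P(radiological response).
#' @param sensitivity,specificity Generative operating point of the
#'   molecular call.
#' @param seed Integer seed.
#' @return Tibble: `patient_id`, `radiological`, `molecular` (logicals).
#' @export
simulate_predictor_labels <- function(n, prevalence = 0.42,
                                      sensitivity = 0.75, specificity = 0.80,
                                      seed = 1) {
  assert_prob(prevalence, "prevalence")
  assert_prob(sensitivity, "sensitivity")
  assert_prob(specificity, "specificity")
  withr::with_seed(seed, {
    truth <- runif(n) < prevalence
    pred <- ifelse(truth, runif(n) < sensitivity, runif(n) > specificity)
    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      radiological = truth,
      molecular = as.logical(pred)
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates every table the downstream analysis consumes: a patient table
#' with RECIST labels, longitudinal SLD and ctDNA series, an expression
#' matrix with two-subtype structure, an immune panel, survival endpoints,
#' and the generative truth table used by recovery tests. Per-patient random
#' substreams are derived from the config seed by counter, so output is
#' independent of generation order and identical for identical seeds.
#'
#' @param config A [cohort_config()].
#' @param immune_effect_map Optional effect map passed to
#'   [simulate_immune_panel()].
#' @param expression_effect_size Marker shift passed to
#'   [simulate_expression_matrix()].
#' @return A list of class `ct_cohort` with elements `patients`, `sld`,
#'   `ctdna`, `immune`, `survival`, `truth`, `expression`, `gene_sets`,
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 12, seed = 7))
#' names(cohort)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            immune_effect_map = NULL,
                            expression_effect_size = 3) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  truth <- withr::with_seed(config$seed, {
    genotype <- sample(names(config$genotype_probs), n, replace = TRUE,
                       prob = config$genotype_probs)
    is_responder <- runif(n) < config$response_prob
    baseline_sld <- rlnorm(n, config$baseline_sld_meanlog,
                           config$baseline_sld_sdlog)
    true_beta <- pmax(rnorm(n, config$coupling_slope_beta, config$beta_sd),
                      0.002)
    baseline_maf <- rlnorm(n, config$baseline_maf_meanlog,
                           config$baseline_maf_sdlog)
    tibble::tibble(
      patient_id = ids, genotype = genotype, is_responder = is_responder,
      baseline_sld = baseline_sld, true_beta = true_beta,
      baseline_maf = baseline_maf,
      # intercept anchors each patient's baseline %MAF at the baseline SLD
      intercept = log10(baseline_maf) - true_beta * baseline_sld,
      rate = ifelse(is_responder, config$growth_rate_responder,
                    config$growth_rate_progressor)
    )
  })

  sld <- purrr::map_dfr(seq_len(n), function(i) {
    tr <- simulate_sld_trajectory(
      truth$baseline_sld[i], truth$rate[i], config$sld_visit_days,
      two_phase = config$two_phase && truth$is_responder[i],
      switch_day = config$switch_day,
      regrowth_rate = abs(config$growth_rate_progressor)
    )
    dplyr::mutate(tr, patient_id = ids[i], .before = 1)
  })

  # ctDNA follows the same latent trajectory sampled on the ctDNA schedule
  ctdna <- purrr::map_dfr(seq_len(n), function(i) {
    latent <- simulate_sld_trajectory(
      truth$baseline_sld[i], truth$rate[i], config$visit_days,
      two_phase = config$two_phase && truth$is_responder[i],
      switch_day = config$switch_day,
      regrowth_rate = abs(config$growth_rate_progressor)
    )
    s_i <- substream_seed(config$seed, i)
    if (truth$genotype[i] == "WT") {
      maf <- withr::with_seed(s_i, {
        pmin(rlnorm(nrow(latent), config$wt_maf_meanlog, config$wt_maf_sdlog),
             100)
      })
      detected <- maf >= config$detection_floor_pct
      ser <- tibble::tibble(day = latent$day,
                            maf_pct = ifelse(detected, maf, 0),
                            detected = detected)
    } else {
      ser <- simulate_ctdna_from_sld(
        latent, truth$true_beta[i], truth$intercept[i],
        config$maf_noise_sd, config$detection_floor_pct, seed = s_i
      )
    }
    dplyr::mutate(ser, patient_id = ids[i], .before = 1)
  })

  recist <- purrr::map_dfr(seq_len(n), function(i) {
    labs <- derive_recist_labels(dplyr::filter(sld, .data$patient_id == ids[i]))
    dplyr::mutate(labs, patient_id = ids[i], .before = 1)
  })

  # sampling stops at treatment discontinuation: SLD at the progression
  # assessment, ctDNA shortly after
  stop_day <- setNames(recist$progression_day, recist$patient_id)
  keep_sld <- is.na(stop_day[sld$patient_id]) |
    sld$day <= stop_day[sld$patient_id]
  sld <- sld[keep_sld, ]
  keep_ct <- is.na(stop_day[ctdna$patient_id]) |
    ctdna$day <= stop_day[ctdna$patient_id] + config$followup_extra_days
  ctdna <- ctdna[keep_ct, ]

  patients <- dplyr::left_join(
    tibble::tibble(patient_id = ids, genotype = truth$genotype),
    recist, by = "patient_id"
  )

  survival <- simulate_survival(
    truth, config$survival_link, config$os_hazard, config$pfs_hazard,
    config$admin_censor_day, seed = substream_seed(config$seed, n + 1)
  )

  classical_genes <- sprintf("CLA%02d", 1:25)
  basal_genes <- sprintf("BAS%02d", 1:25)
  subtype_truth <- ifelse(
    withr::with_seed(substream_seed(config$seed, n + 2), runif(n) < 0.5),
    "classical", "basal-like"
  )
  expression <- simulate_expression_matrix(
    n, subtype_truth, classical_genes, basal_genes,
    effect_size = expression_effect_size,
    seed = substream_seed(config$seed, n + 3)
  )
  expression$sample_ids <- ids
  colnames(expression$values) <- ids

  immune <- simulate_immune_panel(
    dplyr::mutate(truth[, "patient_id"], is_responder = truth$is_responder),
    populations = c("Ki67+ T cells", "Ki67+ NK cells", "CD54+ B cells",
                    "Classical monocytes", "Plasmablasts"),
    effect_map = immune_effect_map,
    seed = substream_seed(config$seed, n + 4)
  )

  truth$subtype <- subtype_truth
  structure(
    list(
      patients = patients, sld = sld, ctdna = ctdna, immune = immune,
      survival = survival, truth = truth, expression = expression,
      gene_sets = list(classical = classical_genes, basal = basal_genes),
      config = config
    ),
    class = "ct_cohort"
  )
}

#' Write a simulated cohort to a directory of plain-text tables
#'
#' Writes `patients.csv`, `sld.csv`, `ctdna.csv`, `immune.csv`,
#' `survival.csv`, `truth.csv`, `expression.tsv` (genes x samples, first
#' column `gene_id`) and `genesets.gmt`.
#'
#' @param cohort A `ct_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ct_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("patients", "sld", "ctdna", "immune", "survival", "truth")) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  expr <- tibble::as_tibble(cohort$expression$values, rownames = "gene_id")
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  gmt <- vapply(names(cohort$gene_sets), function(nm) {
    paste(c(nm, "synthetic marker set", cohort$gene_sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "genesets.gmt"))
  invisible(dir)
}
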