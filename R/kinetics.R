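#' Compute mutant allele fraction (%MAF)
#'
#' %MAF is the mutant copy concentration divided by the total copy
#' concentration, expressed as a percentage.
#'
#' @param mutant_conc Mutant copies/mL (>= 0).
#' @param total_conc Total copies/mL (> 0 whenever `mutant_conc` > 0).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' compute_maf(2, 100)
#' @export
compute_maf <- function(mutant_conc, total_conc) {
  if (any(mutant_conc < 0, na.rm = TRUE)) {
    ck_abort("`mutant_conc` must be >= 0.")
  }
  bad_total <- total_conc <= 0 & mutant_conc > 0
  if (any(bad_total, na.rm = TRUE)) {
    ck_abort("invalid measurement: mutant copies present with total_conc <= 0.")
  }
  if (any(mutant_conc > total_conc, na.rm = TRUE)) {
    ck_abort("invalid measurement: mutant_conc exceeds total_conc.")
  }
  ifelse(total_conc > 0, 100 * mutant_conc / total_conc, 0)
}

# Baseline anchor: latest measurement at day <= 0; if none, the first
# on-treatment measurement is used with a warning.
baseline_value <- function(day, value) {
  pre <- which(day <= 0)
  if (length(pre) > 0) {
    value[pre[which.max(day[pre])]]
  } else {
    rlang::warn("no measurement at day <= 0; using first on-treatment value as baseline.")
    value[which.min(day)]
  }
}

#' Standardize a longitudinal series to its baseline
#'
#' %MAF series are divided by the baseline %MAF (baseline = 1); SLD series
#' are divided by the baseline SLD and expressed as a percentage
#' (baseline = 100). The baseline anchor is the latest measurement at
#' day <= 0.
#'
#' @param series Tibble with a `day` column and the value column for `kind`
#'   (`maf_pct` or `sld_mm`).
#' @param kind `"maf"` or `"sld"`.
#' @return The input tibble with an added `maf_rel` (ratio) or `sld_rel_pct`
#'   (percent) column.
#' @export
standardize_series <- function(series, kind = c("maf", "sld")) {
  kind <- match.arg(kind)
  col <- if (kind == "maf") "maf_pct" else "sld_mm"
  assert_cols(series, c("day", col), "series")
  base <- baseline_value(series$day, series[[col]])
  if (is.na(base) || base <= 0) {
    ck_abort(
      sprintf("baseline %s is zero or missing; patient excluded.", col),
      class = "ctkinetics_exclusion"
    )
  }
  if (kind == "maf") {
    dplyr::mutate(series, maf_rel = .data$maf_pct / base)
  } else {
    dplyr::mutate(series, sld_rel_pct = 100 * .data$sld_mm / base)
  }
}

#' Match tumor-burden assessments to the closest ctDNA measurement
#'
#' Each SLD assessment is paired with the temporally closest %MAF
#' measurement for the same patient; on a tie the earlier %MAF measurement
#' wins (no look-ahead). Pairs with a gap exceeding `max_gap_days` are
#' dropped. Relative columns are computed against each series' own
#' baseline when the baseline is positive.
#'
#' @param sld_series Tibble: `day`, `sld_mm` (one patient).
#' @param maf_series Tibble: `day`, `maf_pct` (one patient).
#' @param max_gap_days Maximum allowed |SLD day - MAF day| (default 21).
#' @return Tibble of paired points: `sld_day`, `maf_day`, `sld_mm`,
#'   `maf_pct`, `sld_rel_pct`, `maf_rel`, `gap_days`. May have zero rows.
#' @seealso [gap_summary()]
#' @export
match_timepoints <- function(sld_series, maf_series, max_gap_days = 21) {
  assert_cols(sld_series, c("day", "sld_mm"), "sld_series")
  assert_cols(maf_series, c("day", "maf_pct"), "maf_series")
  if (nrow(sld_series) == 0 || nrow(maf_series) == 0) {
    ck_abort("both series must be nonempty.")
  }
  sld_series <- dplyr::arrange(sld_series, .data$day)
  maf_series <- dplyr::arrange(maf_series, .data$day)

  sld_base <- baseline_value(sld_series$day, sld_series$sld_mm)
  maf_base <- suppressWarnings(baseline_value(maf_series$day, maf_series$maf_pct))

  idx <- vapply(sld_series$day, function(d) {
    gaps <- abs(maf_series$day - d)
    cand <- which(gaps == min(gaps))
    cand[1]  # series sorted by day: first = earlier measurement on ties
  }, integer(1))

  pairs <- tibble::tibble(
    sld_day = sld_series$day,
    maf_day = maf_series$day[idx],
    sld_mm = sld_series$sld_mm,
    maf_pct = maf_series$maf_pct[idx],
    gap_days = abs(sld_series$day - maf_series$day[idx])
  )
  pairs$sld_rel_pct <- if (!is.na(sld_base) && sld_base > 0) {
    100 * pairs$sld_mm / sld_base
  } else {
    NA_real_
  }
  pairs$maf_rel <- if (!is.na(maf_base) && maf_base > 0) {
    pairs$maf_pct / maf_base
  } else {
    NA_real_
  }
  dplyr::filter(pairs, .data$gap_days <= max_gap_days)
}

#' Summarize pairing gaps
#'
#' @param pairs Output of [match_timepoints()] (possibly row-bound across
#'   patients).
#' @return One-row tibble: `n_pairs`, `mean_gap_days`, `sd_gap_days`.
#' @export
gap_summary <- function(pairs) {
  tibble::tibble(
    n_pairs = nrow(pairs),
    mean_gap_days = mean(pairs$gap_days),
    sd_gap_days = sd(pairs$gap_days)
  )
}

#' Fit a patient-specific exponential %MAF-tumor-burden model
#'
#' Ordinary least squares of `log10(maf_pct + pseudo_maf)` on `sld_mm`.
#' Because %MAF is exponential in SLD, the fit is linear on the log10 scale;
#' `beta` is the per-mm slope and `alpha` the intercept. Only patients with
#' three or more usable points are fit; undetected (zero) %MAF values are
#' excluded unless a positive `pseudo_maf` makes them usable.
#'
#' @param pairs Tibble of paired points with `sld_mm` and `maf_pct`.
#' @param pseudo_maf Additive pseudo-%MAF applied before the log transform
#'   (default 0: zeros are dropped).
#' @param patient_id Optional patient identifier carried into the result.
#' @return One-row tibble: `patient_id`, `alpha`, `beta`, `r2`, `n_points`.
#' @examples
#' sld <- c(20, 40, 60)
#' fit_patient_exponential(
#'   tibble::tibble(sld_mm = sld, maf_pct = 10^(-2 + 0.02 * sld))
#' )
#' @export
fit_patient_exponential <- function(pairs, pseudo_maf = 0,
                                    patient_id = NA_character_) {
  assert_cols(pairs, c("sld_mm", "maf_pct"), "pairs")
  usable <- pairs$maf_pct + pseudo_maf > 0
  pts <- pairs[usable, ]
  if (nrow(pts) < 3) {
    ck_abort("fewer than three usable points; patient excluded from model-based steps.",
             class = "ctkinetics_exclusion")
  }
  y <- log10(pts$maf_pct + pseudo_maf)
  fit <- lm(y ~ sld_mm, data = pts)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  tibble::tibble(
    patient_id = patient_id,
    alpha = unname(coef(fit)[1]),
    beta = unname(coef(fit)[2]),
    r2 = max(min(r2, 1), 0),
    n_points = nrow(pts)
  )
}

#' Fit exponential models for every patient in a cohort
#'
#' Applies [fit_patient_exponential()] per patient; patients with fewer than
#' three usable points are excluded and listed in the `exclusions`
#' attribute.
#'
#' @param pairs Tibble of paired points including `patient_id`.
#' @inheritParams fit_patient_exponential
#' @return An object of class `exp_fit_set`: a tibble of per-patient fits
#'   with an `exclusions` attribute (tibble `patient_id`, `reason`).
#' @export
fit_exponential_models <- function(pairs, pseudo_maf = 0) {
  assert_cols(pairs, c("patient_id", "sld_mm", "maf_pct"), "pairs")
  ids <- unique(pairs$patient_id)
  fits <- list()
  excl <- list()
  for (id in ids) {
    res <- tryCatch(
      fit_patient_exponential(pairs[pairs$patient_id == id, ], pseudo_maf,
                              patient_id = id),
      ctkinetics_exclusion = function(e) e
    )
    if (inherits(res, "condition")) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        patient_id = id, reason = conditionMessage(res)
      )
    } else {
      fits[[length(fits) + 1]] <- res
    }
  }
  out <- if (length(fits)) dplyr::bind_rows(fits) else
    tibble::tibble(patient_id = character(), alpha = numeric(),
                   beta = numeric(), r2 = numeric(), n_points = integer())
  structure(out,
            exclusions = if (length(excl)) dplyr::bind_rows(excl) else
              tibble::tibble(patient_id = character(), reason = character()),
            class = c("exp_fit_set", class(out)))
}

#' @export
tidy.exp_fit_set <- function(x, ...) {
  tibble::as_tibble(unclass(x)[!names(unclass(x)) %in% "exclusions"])
}

#' @export
glance.exp_fit_set <- function(x, ...) {
  tibble::tibble(
    n_fit = nrow(x),
    n_excluded = nrow(attr(x, "exclusions")),
    mean_beta = mean(x$beta),
    mean_r2 = mean(x$r2)
  )
}

#' Translate a tumor-burden reduction into %MAF reductions
#'
#' Uses the patient-specific exponential models to express a fractional SLD
#' reduction (default the RECIST partial-response threshold, 30%) as the
#' equivalent %MAF reduction per patient:
#' `100 * (1 - 10^(beta * (-sld_reduction * sld0)))`.
#'
#' @param fits Tibble with `patient_id` and `beta` (e.g. an `exp_fit_set`).
#' @param baselines Tibble with `patient_id` and `sld0` (baseline SLD, mm).
#' @param sld_reduction Fractional SLD reduction to translate (default 0.30).
#' @return A list: `per_patient` (tibble `patient_id`,
#'   `maf_reduction_pct`), `mean`, `sd`, and `skipped` (patients without a
#'   positive baseline).
#' @export
translate_sld_threshold <- function(fits, baselines, sld_reduction = 0.30) {
  assert_cols(fits, c("patient_id", "beta"), "fits")
  assert_cols(baselines, c("patient_id", "sld0"), "baselines")
  joined <- dplyr::inner_join(
    tibble::as_tibble(fits[, c("patient_id", "beta")]),
    baselines, by = "patient_id"
  )
  skipped <- dplyr::union(
    setdiff(fits$patient_id, baselines$patient_id),
    joined$patient_id[is.na(joined$sld0) | joined$sld0 <= 0]
  )
  if (length(skipped) > 0) {
    rlang::inform(sprintf("skipping %d patient(s) without a positive baseline SLD.",
                          length(skipped)))
  }
  ok <- dplyr::filter(joined, !is.na(.data$sld0) & .data$sld0 > 0)
  per <- tibble::tibble(
    patient_id = ok$patient_id,
    maf_reduction_pct = 100 * (1 - 10^(ok$beta * (-sld_reduction * ok$sld0)))
  )
  list(
    per_patient = per,
    mean = mean(per$maf_reduction_pct),
    sd = sd(per$maf_reduction_pct),
    skipped = skipped
  )
}

#' Correlate %MAF with tumor burden
#'
#' Pearson correlation of SLD against log10(%MAF) on the absolute scale and
#' of %SLD (percent of baseline) against %MAF relative to baseline, with
#' two-sided p-values.
#'
#' @param pairs Tibble of paired points (`sld_mm`, `maf_pct`, and for the
#'   relative scale `sld_rel_pct`, `maf_rel`). Undetected (zero) %MAF points
#'   are excluded from the absolute (log) scale.
#' @return Tibble with one row per scale: `scale`, `r`, `p`, `n`.
#' @export
correlate_maf_sld <- function(pairs) {
  assert_cols(pairs, c("sld_mm", "maf_pct"), "pairs")
  det <- dplyr::filter(pairs, .data$maf_pct > 0)
  if (nrow(det) < 3) {
    ck_abort("need at least three pairs with detected %MAF.")
  }
  one_scale <- function(x, y, label) {
    if (sd(x) == 0 || sd(y) == 0) {
      ck_abort(sprintf("zero variance on the %s scale.", label))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(scale = label, r = unname(ct$estimate),
                   p = ct$p.value, n = length(x))
  }
  out <- one_scale(det$sld_mm, log10(det$maf_pct), "absolute")
  if (all(c("sld_rel_pct", "maf_rel") %in% names(pairs))) {
    rel <- dplyr::filter(pairs, !is.na(.data$sld_rel_pct) & !is.na(.data$maf_rel))
    if (nrow(rel) >= 3) {
      out <- dplyr::bind_rows(
        out, one_scale(rel$sld_rel_pct, rel$maf_rel, "relative")
      )
    }
  }
  out
}
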