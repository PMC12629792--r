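#' Configuration for molecular response/progression/clearance calling
#'
#' Default thresholds follow the calibrated convention for KRAS-mutant
#' ctDNA monitoring: molecular response is a >= 90% reduction from baseline
#' in %MAF within the first 70 days; molecular progression is a >= 10%
#' increase from any previous measurement within the first 225 days;
#' clearance is %MAF at or below the wild-type background threshold within
#' the first 225 days.
#'
#' @param mresponse_reduction Minimum fractional %MAF reduction from
#'   baseline for a molecular response (default 0.90).
#' @param mresponse_window_days Molecular response window (default 70).
#' @param mprogression_increase Minimum %MAF increase for molecular
#'   progression (default 0.10).
#' @param mprogression_mode `"relative"` (increase by a factor
#'   `1 + mprogression_increase` over a previous measurement, default) or
#'   `"absolute_points"` (increase by `100 * mprogression_increase`
#'   percentage points).
#' @param mprogression_window_days Molecular progression window (default 225).
#' @param clearance_window_days Clearance window (default 225).
#' @param clearance_threshold %MAF at or below which ctDNA counts as
#'   cleared; typically from [compute_clearance_threshold()].
#' @return A list of class `molecular_call_config`.
#' @export
molecular_call_config <- function(mresponse_reduction = 0.90,
                                  mresponse_window_days = 70,
                                  mprogression_increase = 0.10,
                                  mprogression_mode = c("relative",
                                                        "absolute_points"),
                                  mprogression_window_days = 225,
                                  clearance_window_days = 225,
                                  clearance_threshold = 0) {
  mprogression_mode <- match.arg(mprogression_mode)
  if (mresponse_reduction <= 0 || mresponse_reduction > 1) {
    ck_abort("`mresponse_reduction` must be in (0, 1].")
  }
  if (mprogression_increase <= 0 || mprogression_increase > 1) {
    ck_abort("`mprogression_increase` must be in (0, 1].")
  }
  if (mresponse_window_days <= 0 || mprogression_window_days <= 0 ||
      clearance_window_days <= 0) {
    ck_abort("all windows must be > 0.")
  }
  if (clearance_threshold < 0) ck_abort("`clearance_threshold` must be >= 0.")
  structure(
    list(
      mresponse_reduction = mresponse_reduction,
      mresponse_window_days = mresponse_window_days,
      mprogression_increase = mprogression_increase,
      mprogression_mode = mprogression_mode,
      mprogression_window_days = mprogression_window_days,
      clearance_window_days = clearance_window_days,
      clearance_threshold = clearance_threshold
    ),
    class = "molecular_call_config"
  )
}

#' Read a molecular call configuration from a YAML file
#'
#' The file may set any subset of the [molecular_call_config()] fields;
#' unset fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `molecular_call_config`.
#' @export
read_call_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(molecular_call_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    ck_abort(sprintf("unknown config field(s): %s.",
                     paste(unknown, collapse = ", ")))
  }
  do.call(molecular_call_config, vals)
}

#' Compute the ctDNA clearance threshold from wild-type background
#'
#' The clearance threshold is the mean of %MAF measurements from KRAS
#' wild-type patients plus three sample standard deviations (the assay's
#' background level).
#'
#' @param wt_maf Numeric vector of %MAF measurements from wild-type
#'   patients (>= 2 values).
#' @return The threshold as a single %MAF value.
#' @examples
#' compute_clearance_threshold(c(0.01, 0.02, 0.03))
#' @export
compute_clearance_threshold <- function(wt_maf) {
  wt_maf <- wt_maf[!is.na(wt_maf)]
  if (length(wt_maf) < 2) {
    ck_abort("need at least two wild-type measurements to compute a threshold.")
  }
  mean(wt_maf) + 3 * sd(wt_maf)
}

# Shared helper: sorted series with baseline anchor; errors are exclusions.
split_series <- function(series) {
  assert_cols(series, c("day", "maf_pct"), "series")
  series <- dplyr::arrange(series, .data$day)
  pre <- which(series$day <= 0)
  baseline <- if (length(pre) > 0) series$maf_pct[max(pre)] else NA_real_
  list(baseline = baseline, on = dplyr::filter(series, .data$day > 0))
}

#' Call ctDNA clearance for one patient
#'
#' A patient is cleared when any on-treatment %MAF measurement falls to or
#' below the clearance threshold within the clearance window. Patients whose
#' baseline %MAF is not above the threshold are not evaluable.
#'
#' @param series Tibble with `day`, `maf_pct` for one patient, including a
#'   baseline row at day <= 0.
#' @param config A [molecular_call_config()].
#' @return One-row tibble: `evaluable`, `cleared`, `first_clearance_day`.
#' @export
call_clearance <- function(series, config = molecular_call_config()) {
  s <- split_series(series)
  if (is.na(s$baseline) || s$baseline <= config$clearance_threshold) {
    return(tibble::tibble(evaluable = FALSE, cleared = NA,
                          first_clearance_day = NA_real_))
  }
  hit <- s$on$maf_pct <= config$clearance_threshold &
    s$on$day <= config$clearance_window_days
  tibble::tibble(
    evaluable = TRUE,
    cleared = any(hit),
    first_clearance_day = if (any(hit)) s$on$day[which(hit)[1]] else NA_real_
  )
}

#' Call molecular response for one patient
#'
#' Molecular response: %MAF reduced from baseline by at least
#' `mresponse_reduction` (default 90%) at some measurement within the first
#' `mresponse_window_days` (default 70) days.
#'
#' @inheritParams call_clearance
#' @return One-row tibble: `evaluable`, `mresponse`, `mresponse_day`.
#' @export
call_mresponse <- function(series, config = molecular_call_config()) {
  s <- split_series(series)
  if (is.na(s$baseline) || s$baseline <= 0) {
    return(tibble::tibble(evaluable = FALSE, mresponse = NA,
                          mresponse_day = NA_real_))
  }
  rel <- s$on$maf_pct / s$baseline
  hit <- rel <= (1 - config$mresponse_reduction) &
    s$on$day <= config$mresponse_window_days
  tibble::tibble(
    evaluable = TRUE,
    mresponse = any(hit),
    mresponse_day = if (any(hit)) s$on$day[which(hit)[1]] else NA_real_
  )
}

#' Call molecular progression for one patient
#'
#' Molecular progression: %MAF increases by at least
#' `mprogression_increase` over *any* previous measurement (baseline
#' included), at a measurement within the first `mprogression_window_days`
#' (default 225) days. In `"relative"` mode the increase is a factor
#' (`maf_i >= (1 + increase) * maf_j` with `maf_j > 0`); in
#' `"absolute_points"` mode it is in percentage points.
#'
#' @inheritParams call_clearance
#' @return One-row tibble: `evaluable`, `mprogression`, `mprogression_day`.
#' @export
call_mprogression <- function(series, config = molecular_call_config()) {
  s <- split_series(series)
  all_pts <- dplyr::bind_rows(
    if (!is.na(s$baseline)) tibble::tibble(day = 0, maf_pct = s$baseline),
    s$on[, c("day", "maf_pct")]
  )
  if (nrow(all_pts) < 2) {
    return(tibble::tibble(evaluable = FALSE, mprogression = NA,
                          mprogression_day = NA_real_))
  }
  first_day <- NA_real_
  for (i in 2:nrow(all_pts)) {
    # only on-treatment measurements inside the window can qualify;
    # any earlier measurement serves as the comparator
    if (all_pts$day[i] <= 0 ||
        all_pts$day[i] > config$mprogression_window_days) next
    prev <- all_pts$maf_pct[seq_len(i - 1)]
    cur <- all_pts$maf_pct[i]
    hit <- if (config$mprogression_mode == "relative") {
      any(prev > 0 & cur >= (1 + config$mprogression_increase) * prev)
    } else {
      any(cur - prev >= 100 * config$mprogression_increase)
    }
    if (hit) {
      first_day <- all_pts$day[i]
      break
    }
  }
  tibble::tibble(
    evaluable = TRUE,
    mprogression = !is.na(first_day),
    mprogression_day = first_day
  )
}

#' Call clearance, molecular response and molecular progression cohort-wide
#'
#' Applies [call_clearance()], [call_mresponse()] and [call_mprogression()]
#' to every patient in a long ctDNA table. When `config$clearance_threshold`
#' is not supplied and a `genotype` column identifies wild-type (`"WT"`)
#' patients, the clearance threshold is computed from all their
#' measurements via [compute_clearance_threshold()]; wild-type patients are
#' then excluded from calling.
#'
#' @param ctdna Long tibble: `patient_id`, `day`, `maf_pct`, optionally
#'   `genotype`.
#' @param config A [molecular_call_config()].
#' @return An object of class `molecular_calls`: a tibble with one row per
#'   patient (`patient_id`, `evaluable`, `cleared`, `first_clearance_day`,
#'   `mresponse`, `mresponse_day`, `mprogression`, `mprogression_day`) with
#'   the config (including the threshold used) in the `config` attribute.
#' @export
call_molecular <- function(ctdna, config = molecular_call_config()) {
  assert_cols(ctdna, c("patient_id", "day", "maf_pct"), "ctdna")
  if ("genotype" %in% names(ctdna) && config$clearance_threshold == 0 &&
      any(ctdna$genotype == "WT")) {
    thr <- compute_clearance_threshold(
      ctdna$maf_pct[ctdna$genotype == "WT"]
    )
    config$clearance_threshold <- thr
    ctdna <- dplyr::filter(ctdna, .data$genotype != "WT")
  }
  out <- ctdna |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      cl <- call_clearance(df, config)
      mr <- call_mresponse(df, config)
      mp <- call_mprogression(df, config)
      tibble::tibble(
        evaluable = cl$evaluable & mr$evaluable,
        cleared = cl$cleared, first_clearance_day = cl$first_clearance_day,
        mresponse = mr$mresponse, mresponse_day = mr$mresponse_day,
        mprogression = mp$mprogression,
        mprogression_day = mp$mprogression_day
      )
    }) |>
    dplyr::ungroup()
  structure(out, config = config,
            class = c("molecular_calls", class(out)))
}

#' @export
tidy.molecular_calls <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.molecular_calls <- function(x, ...) {
  ev <- x[x$evaluable, ]
  tibble::tibble(
    n_patients = nrow(x),
    n_evaluable = nrow(ev),
    n_cleared = sum(ev$cleared, na.rm = TRUE),
    n_mresponse = sum(ev$mresponse, na.rm = TRUE),
    n_mprogression = sum(ev$mprogression, na.rm = TRUE),
    clearance_threshold = attr(x, "config")$clearance_threshold
  )
}
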