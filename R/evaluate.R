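#' Evaluate a molecular call against a radiological reference
#'
#' Builds the confusion matrix of a binary molecular call (e.g. molecular
#' response) against the radiological reference label (e.g. confirmed
#' RECIST response) on the same patients and reports accuracy, sensitivity
#' and specificity as percentages.
#'
#' @param molecular Logical vector of molecular calls.
#' @param radiological Logical vector of radiological labels, same patients
#'   in the same order. No missing values allowed.
#' @return An object of class `predictor_eval`: a list with counts `tp`,
#'   `fn`, `fp`, `tn` and exact percentages `accuracy`, `sensitivity`,
#'   `specificity`. `glance()` reports the percentages rounded to one
#'   decimal (half away from zero), the conventional reporting precision.
#' @examples
#' ev <- evaluate_predictor(
#'   molecular = rep(c(TRUE, FALSE), c(20, 23)),
#'   radiological = rep(c(TRUE, FALSE, TRUE, FALSE), c(16, 4, 6, 17))
#' )
#' glance(ev)
#' @export
evaluate_predictor <- function(molecular, radiological) {
  if (length(molecular) != length(radiological)) {
    ck_abort("`molecular` and `radiological` must cover the same patients.")
  }
  if (anyNA(molecular) || anyNA(radiological)) {
    ck_abort("missing labels are not allowed; exclude those patients first.")
  }
  tp <- sum(molecular & radiological)
  fn <- sum(!molecular & radiological)
  fp <- sum(molecular & !radiological)
  tn <- sum(!molecular & !radiological)
  n <- tp + fn + fp + tn
  structure(
    list(
      tp = tp, fn = fn, fp = fp, tn = tn, n = n,
      accuracy = 100 * (tp + tn) / n,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    ),
    class = "predictor_eval"
  )
}

#' @export
print.predictor_eval <- function(x, ...) {
  cat(sprintf(
    "Predictor evaluation (n = %d)\n  TP %d  FN %d  FP %d  TN %d\n  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
    x$n, x$tp, x$fn, x$fp, x$tn,
    round_half_out(x$accuracy), round_half_out(x$sensitivity),
    round_half_out(x$specificity)
  ))
  invisible(x)
}

#' @export
tidy.predictor_eval <- function(x, ...) {
  tibble::tibble(
    molecular = c(TRUE, FALSE, TRUE, FALSE),
    radiological = c(TRUE, TRUE, FALSE, FALSE),
    count = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' @export
glance.predictor_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    accuracy = round_half_out(x$accuracy),
    sensitivity = round_half_out(x$sensitivity),
    specificity = round_half_out(x$specificity)
  )
}

#' Lead time of a molecular call over the radiological call
#'
#' Positive values mean the molecular call came first.
#'
#' @param molecular_day Day of the molecular call per patient.
#' @param radiological_day Day of the radiological call per patient.
#' @return Numeric vector `radiological_day - molecular_day`; `NA` where
#'   either day is missing.
#' @examples
#' compute_lead_time(20, 67)
#' @export
compute_lead_time <- function(molecular_day, radiological_day) {
  radiological_day - molecular_day
}

#' Summarize lead times over patients with both events
#'
#' @param lead_time_days Vector from [compute_lead_time()]; `NA` entries
#'   (patients missing either event) are excluded.
#' @return One-row tibble: `n`, `mean_days`, `sd_days`.
#' @export
lead_time_summary <- function(lead_time_days) {
  x <- lead_time_days[!is.na(lead_time_days)]
  tibble::tibble(n = length(x), mean_days = mean(x), sd_days = sd(x))
}
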