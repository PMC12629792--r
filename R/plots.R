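#' Scatter plot of tumor burden against log10 %MAF
#'
#' Visualizes the exponential coupling between SLD and ctDNA %MAF as the
#' linear relationship on the log10 scale, with one least-squares line per
#' patient when `by_patient = TRUE`.
#'
#' @param pairs Paired points (e.g. from [pair_cohort()]); undetected
#'   (zero) %MAF points are dropped.
#' @param by_patient Color and fit per patient (default `TRUE` when a
#'   `patient_id` column is present).
#' @return A ggplot object.
#' @export
plot_maf_sld <- function(pairs, by_patient = "patient_id" %in% names(pairs)) {
  det <- dplyr::filter(pairs, .data$maf_pct > 0)
  p <- ggplot2::ggplot(det, ggplot2::aes(x = .data$sld_mm,
                                         y = log10(.data$maf_pct)))
  if (by_patient) {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(color = .data$patient_id),
                          show.legend = FALSE) +
      ggplot2::geom_smooth(ggplot2::aes(group = .data$patient_id),
                           method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.3, color = "grey40")
  } else {
    p <- p + ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x)
  }
  p + ggplot2::labs(x = "SLD (mm)", y = "log10(%MAF)")
}

#' Kaplan-Meier plot by stratum
#'
#' @param time,event,group Survival data as in [weighted_logrank_test()].
#' @return A ggplot step-curve object.
#' @export
plot_km <- function(time, event, group) {
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble::tibble(time = fit$time, surv = fit$surv,
                       stratum = sub("^group=", "", strata))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Days", y = "Survival probability", color = NULL)
}

#' Autoplot a predictor evaluation as a confusion-matrix tile plot
#'
#' @param object A `predictor_eval` from [evaluate_predictor()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.predictor_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$radiological, y = .data$molecular,
    fill = .data$count, label = .data$count
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(color = "white") +
    ggplot2::labs(x = "Radiological", y = "Molecular call", fill = "n")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
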