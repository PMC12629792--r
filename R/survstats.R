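#' Kaplan-Meier estimate with median and 95% CI
#'
#' Product-limit estimator via [survival::survfit()] with log-log
#' (Greenwood-based) confidence intervals. The median is the smallest time
#' with survival at or below 0.5; `NA` when the curve never reaches 0.5.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return A list: `curve` (tibble `time`, `n_risk`, `n_event`, `surv`,
#'   `lower`, `upper`), `median`, `median_lower`, `median_upper`.
#' @export
km_estimate <- function(time, event) {
  if (any(time <= 0)) ck_abort("`time` must be > 0.")
  if (!all(event %in% c(0, 1))) ck_abort("`event` must be 0/1.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  # median as the smallest time with S(t) <= 0.5 (not the midpoint
  # interpolation survfit reports when the curve sits exactly at 0.5)
  below <- which(fit$surv <= 0.5)
  list(
    curve = tibble::tibble(
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      surv = fit$surv, lower = fit$lower, upper = fit$upper
    ),
    median = if (length(below) > 0) fit$time[below[1]] else NA_real_,
    median_lower = unname(tab["0.95LCL"]),
    median_upper = unname(tab["0.95UCL"])
  )
}

#' Weighted log-rank test (log-rank and Gehan-Breslow)
#'
#' Two-or-more-group weighted log-rank test. With unit weights this is the
#' classic log-rank test; with weights equal to the total number at risk at
#' each event time it is the Gehan-Breslow generalized Wilcoxon test, which
#' emphasizes early differences between curves.
#'
#' @param time Follow-up times.
#' @param event Event indicator (1 = event, 0 = censored); at least one
#'   event required.
#' @param group Group labels (>= 2 distinct values).
#' @param weights `"logrank"` (unit weights) or `"gehan"` (number at risk).
#' @return A list: `chi2`, `df`, `p` (two-sided), `weights`.
#' @export
weighted_logrank_test <- function(time, event, group,
                                  weights = c("logrank", "gehan")) {
  weights <- match.arg(weights)
  g <- factor(group)
  k <- nlevels(g)
  if (k < 2) ck_abort("need at least two groups.")
  if (sum(event) == 0) ck_abort("need at least one event.")
  et <- sort(unique(time[event == 1]))
  u <- numeric(k - 1)
  v <- matrix(0, k - 1, k - 1)
  for (t in et) {
    at <- time >= t
    n <- sum(at)
    d <- sum(time == t & event == 1)
    if (n <= 1) next
    nk <- vapply(levels(g), function(l) sum(at & g == l), numeric(1))
    dk <- vapply(levels(g), function(l) sum(time == t & event == 1 & g == l),
                 numeric(1))
    w <- if (weights == "gehan") n else 1
    e <- d * nk / n
    # hypergeometric covariance of the group event counts at this time
    p <- nk / n
    vi <- d * (n - d) / (n - 1) * (diag(p) - tcrossprod(p))
    u <- u + w * (dk - e)[seq_len(k - 1)]
    v <- v + w^2 * vi[seq_len(k - 1), seq_len(k - 1), drop = FALSE]
  }
  chi2 <- drop(t(u) %*% solve(v, u))
  list(chi2 = chi2, df = k - 1,
       p = pchisq(chi2, k - 1, lower.tail = FALSE), weights = weights)
}

#' Cox proportional hazards fit with tidy output
#'
#' Partial-likelihood Cox model (Breslow tie handling) via
#' [survival::coxph()], supporting continuous and categorical covariates and
#' interaction terms through the usual formula interface. Monotone
#' likelihood (separation) surfaces as the underlying fitter's warning and
#' estimates are still reported.
#'
#' @param formula A [survival::Surv()] formula, e.g.
#'   `Surv(os_days, os_event) ~ subtype * ecm_score`.
#' @param data Data frame with the modelling columns. Set factor reference
#'   levels (e.g. `"classical"`, `"G12V"`) before fitting with
#'   [stats::relevel()].
#' @return Tibble with one row per model term: `term`, `hr`, `ci_low`,
#'   `ci_high`, `p` (Wald), `log_hr`, `se`.
#' @export
cox_fit <- function(formula, data) {
  fit <- survival::coxph(formula, data = data, ties = "breslow")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  tibble::tibble(
    term = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    log_hr = unname(co[, "coef"]),
    se = unname(co[, "se(coef)"])
  )
}
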