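#' Per-patient fold change between two immune-panel visits
#'
#' Fold change = value at the target visit divided by the value at the
#' baseline visit, per (patient, population). Rows with a zero baseline or a
#' missing visit are excluded and listed in the `excluded` attribute.
#'
#' @param panel Long tibble: `patient_id`, `day_label`, `population`,
#'   `frequency`.
#' @param baseline_day Baseline visit label (e.g. `"C1D1"`).
#' @param target_day Target visit label (e.g. `"C1D2"`).
#' @return Tibble: `patient_id`, `population`, `baseline`, `target`, `fc`.
#' @export
fold_change_table <- function(panel, baseline_day = "C1D1",
                              target_day = "C1D2") {
  assert_cols(panel, c("patient_id", "day_label", "population", "frequency"),
              "panel")
  if (!all(c(baseline_day, target_day) %in% panel$day_label)) {
    ck_abort("unknown day label: baseline or target visit absent from panel.")
  }
  wide <- panel |>
    dplyr::filter(.data$day_label %in% c(baseline_day, target_day)) |>
    tidyr::pivot_wider(
      id_cols = c("patient_id", "population"),
      names_from = "day_label", values_from = "frequency"
    )
  wide$baseline <- wide[[baseline_day]]
  wide$target <- wide[[target_day]]
  bad <- is.na(wide$baseline) | is.na(wide$target) | wide$baseline <= 0
  excluded <- wide[bad, c("patient_id", "population")]
  out <- wide[!bad, ] |>
    dplyr::mutate(fc = .data$target / .data$baseline) |>
    dplyr::select("patient_id", "population", "baseline", "target", "fc")
  attr(out, "excluded") <- excluded
  out
}

#' Normality-gated two-group comparison
#'
#' Distribution of each group is evaluated by the Shapiro-Wilk test; when
#' both groups look normal (Shapiro p >= `alpha_normality`) a two-sample
#' t-test is used, otherwise the Wilcoxon rank-sum test. Degenerate groups
#' (all values identical, where Shapiro-Wilk is undefined) route to the
#' rank-based branch.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 3.
#' @param alpha_normality Shapiro-Wilk significance gate (default 0.05).
#' @return A list: `test_used` (`"t"` or `"wilcoxon"`), `p`,
#'   `shapiro_p_a`, `shapiro_p_b`.
#' @export
normality_gated_compare <- function(group_a, group_b,
                                    alpha_normality = 0.05) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    ck_abort("each group needs at least three values.")
  }
  sh <- function(x) {
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  pa <- sh(group_a)
  pb <- sh(group_b)
  if (pa >= alpha_normality && pb >= alpha_normality) {
    res <- t.test(group_a, group_b)
    list(test_used = "t", p = res$p.value, shapiro_p_a = pa, shapiro_p_b = pb)
  } else {
    res <- suppressWarnings(wilcox.test(group_a, group_b))
    list(test_used = "wilcoxon", p = res$p.value,
         shapiro_p_a = pa, shapiro_p_b = pb)
  }
}

#' K-means clustering of samples on a fold-change matrix
#'
#' Deterministic given the seed; multiple random restarts as in the subtype
#' module.
#'
#' @param fc_matrix Samples x variables numeric matrix (finite values).
#' @param k Number of clusters (default 2); must not exceed the number of
#'   samples.
#' @param nstart Restarts (default 50).
#' @param seed Integer seed.
#' @return Integer vector of cluster labels, named by rownames of
#'   `fc_matrix` when present.
#' @export
kmeans_cluster_samples <- function(fc_matrix, k = 2, nstart = 50, seed = 1) {
  fc_matrix <- as.matrix(fc_matrix)
  if (any(!is.finite(fc_matrix))) ck_abort("`fc_matrix` must be finite.")
  if (k > nrow(fc_matrix)) ck_abort("`k` exceeds the number of samples.")
  km <- withr::with_seed(seed, kmeans(fc_matrix, centers = k, nstart = nstart))
  setNames(km$cluster, rownames(fc_matrix))
}
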