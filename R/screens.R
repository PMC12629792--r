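#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by summing hypergeometric probabilities no larger
#' than the observed table's probability (the convention of
#' [stats::fisher.test()], which backs this function), with the conditional
#' maximum-likelihood odds ratio. Tables with a zero margin carry no
#' information: p = 1 and the odds ratio is undefined (`NA`).
#'
#' @param table A 2x2 matrix of nonnegative integer counts, or the four
#'   counts `a, b, c, d` (row-wise).
#' @return A list: `odds_ratio` (conditional MLE), `p`.
#' @examples
#' fisher_exact_test(matrix(c(17, 9, 3, 9), 2))
#' @export
fisher_exact_test <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table))) {
    ck_abort("`table` must be a 2x2 matrix of nonnegative integer counts.")
  }
  if (sum(table) == 0) ck_abort("table total must be > 0.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement (via
#' [stats::p.adjust()]); input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    ck_abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Fisher screen of binary features against categorical endpoints
#'
#' One Fisher's exact test per (feature, endpoint) pair. Features present in
#' fewer than `min_altered` samples (default 3) are excluded before testing
#' and listed in the `excluded` attribute; constant endpoints are skipped
#' with a warning. Raw p-values and BH q-values (adjusted within each
#' endpoint family) are reported.
#'
#' @param features Samples x features binary (0/1 or logical) data frame or
#'   matrix with sample rows aligned to `endpoints`.
#' @param endpoints Data frame of categorical endpoints (two levels each),
#'   one row per sample.
#' @param min_altered Minimum number of altered samples for a feature to be
#'   tested (default 3).
#' @return Tibble: `feature`, `endpoint`, `odds_ratio`, `p`, `q`, with
#'   attribute `excluded` naming dropped features.
#' @export
fisher_screen <- function(features, endpoints, min_altered = 3) {
  features <- as.data.frame(features)
  endpoints <- as.data.frame(endpoints)
  if (nrow(features) != nrow(endpoints)) {
    ck_abort("`features` and `endpoints` must have the same samples.")
  }
  n_alt <- vapply(features, function(x) sum(x > 0), numeric(1))
  excluded <- names(features)[n_alt < min_altered]
  kept <- setdiff(names(features), excluded)
  out <- list()
  for (ep in names(endpoints)) {
    y <- factor(endpoints[[ep]])
    if (nlevels(y) < 2) {
      rlang::warn(sprintf("endpoint '%s' is constant; skipped.", ep))
      next
    }
    for (f in kept) {
      x <- factor(as.integer(features[[f]] > 0), levels = c(0, 1))
      ft <- fisher_exact_test(as.matrix(table(x, y)))
      out[[length(out) + 1]] <- tibble::tibble(
        feature = f, endpoint = ep,
        odds_ratio = ft$odds_ratio, p = ft$p
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) {
    res <- res |>
      dplyr::group_by(.data$endpoint) |>
      dplyr::mutate(q = bh_adjust(.data$p)) |>
      dplyr::ungroup()
  }
  attr(res, "excluded") <- excluded
  res
}

#' Pairwise confounding screen over mixed-type covariates
#'
#' Tests every pair of covariates for association: numeric-numeric pairs by
#' Pearson correlation, categorical-categorical pairs by Fisher's exact test
#' when any expected cell count is below 5 and by chi-square otherwise, and
#' categorical-numeric pairs by one-way ANOVA. P-values are BH-adjusted over
#' the whole screen. Covariates with a single level are skipped with a
#' warning.
#'
#' @param covariates Data frame; columns of type factor/character are
#'   treated as categorical, numeric columns as numerical.
#' @return Tibble: `var1`, `var2`, `test`, `statistic`, `p`, `q`.
#' @export
confounding_screen <- function(covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) ck_abort("need at least two covariates.")
  is_cat <- vapply(covariates, function(x) is.factor(x) || is.character(x),
                   logical(1))
  usable <- vapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    if (is_cat[nm]) {
      ok <- length(unique(na.omit(x))) >= 2
    } else {
      ok <- sd(x, na.rm = TRUE) > 0
    }
    if (!ok) rlang::warn(sprintf("covariate '%s' has a single level; skipped.", nm))
    ok
  }, logical(1))
  vars <- names(covariates)[usable]
  out <- list()
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      v1 <- vars[i]; v2 <- vars[j]
      x <- covariates[[v1]]; y <- covariates[[v2]]
      if (!is_cat[v1] && !is_cat[v2]) {
        ct <- cor.test(x, y, method = "pearson")
        row <- tibble::tibble(var1 = v1, var2 = v2, test = "pearson",
                              statistic = unname(ct$estimate), p = ct$p.value)
      } else if (is_cat[v1] && is_cat[v2]) {
        tab <- table(factor(x), factor(y))
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          ft <- fisher.test(tab)
          row <- tibble::tibble(var1 = v1, var2 = v2, test = "fisher",
                                statistic = NA_real_, p = ft$p.value)
        } else {
          cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
          row <- tibble::tibble(var1 = v1, var2 = v2, test = "chisq",
                                statistic = unname(cs$statistic),
                                p = cs$p.value)
        }
      } else {
        num <- if (is_cat[v1]) y else x
        cat_ <- factor(if (is_cat[v1]) x else y)
        a <- anova(lm(num ~ cat_))
        row <- tibble::tibble(var1 = v1, var2 = v2, test = "anova",
                              statistic = a[["F value"]][1],
                              p = a[["Pr(>F)"]][1])
      }
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(var1 = character(), var2 = character(),
                          test = character(), statistic = numeric(),
                          p = numeric(), q = numeric()))
  }
  res <- dplyr::bind_rows(out)
  res$q <- bh_adjust(res$p)
  res
}
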