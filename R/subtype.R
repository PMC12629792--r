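#' Z-score transform expression rows
#'
#' Centers and scales each gene (row) to mean 0 and sample standard
#' deviation 1 across samples, optionally restricted to a gene subset.
#' Zero-variance genes are dropped with a warning; requested genes absent
#' from the matrix are reported via a message.
#'
#' @param values Numeric genes x samples matrix with rownames.
#' @param gene_subset Optional character vector of gene IDs to keep.
#' @return The z-scored submatrix.
#' @export
zscore_transform <- function(values, gene_subset = NULL) {
  if (is.null(rownames(values))) ck_abort("`values` must have gene rownames.")
  if (!is.null(gene_subset)) {
    absent <- setdiff(gene_subset, rownames(values))
    if (length(absent) > 0) {
      rlang::inform(sprintf("%d requested gene(s) absent from the matrix.",
                            length(absent)))
    }
    values <- values[intersect(gene_subset, rownames(values)), , drop = FALSE]
  }
  sds <- apply(values, 1, sd)
  if (any(sds == 0)) {
    rlang::warn(sprintf("dropping %d zero-variance gene(s).", sum(sds == 0)))
    values <- values[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (values - rowMeans(values)) / sds
}

#' Classify samples into classical vs. basal-like molecular subtypes
#'
#' Z-scores the signature genes, projects samples into PCA space, partitions
#' them with K-means (k = 2, multiple restarts, seeded), and labels the
#' cluster with the higher mean z-score over the classical signature as
#' `"classical"`, the other as `"basal-like"`.
#'
#' @param values Genes x samples expression matrix (VST-like scale).
#' @param classical_set,basal_set Character vectors of signature gene IDs.
#' @param n_pcs Number of principal components used for clustering
#'   (default 2; reduced with a warning if fewer are available).
#' @param k Number of clusters (default 2).
#' @param nstart K-means restarts (default 50).
#' @param seed Integer seed making the clustering deterministic.
#' @return Tibble: `sample_id`, `subtype`, `cluster_index`, and the PC
#'   coordinates `pc1..pcN`.
#' @export
classify_molecular_subtype <- function(values, classical_set, basal_set,
                                       n_pcs = 2, k = 2, nstart = 50,
                                       seed = 1) {
  sig <- union(classical_set, basal_set)
  z <- zscore_transform(values, sig)
  if (nrow(z) < 2) ck_abort("need at least two signature genes present.")
  if (ncol(z) < k) ck_abort("need at least `k` samples.")
  pca <- prcomp(t(z), center = FALSE, scale. = FALSE)
  avail <- ncol(pca$x)
  if (avail < n_pcs) {
    rlang::warn(sprintf("only %d PC(s) available; reducing n_pcs.", avail))
    n_pcs <- avail
  }
  coords <- pca$x[, seq_len(n_pcs), drop = FALSE]
  km <- withr::with_seed(seed, kmeans(coords, centers = k, nstart = nstart))
  cl_genes <- intersect(classical_set, rownames(z))
  mean_classical <- vapply(seq_len(k), function(cl) {
    mean(z[cl_genes, km$cluster == cl, drop = FALSE])
  }, numeric(1))
  classical_cluster <- which.max(mean_classical)
  cluster <- unname(km$cluster)
  out <- tibble::tibble(
    sample_id = colnames(z),
    subtype = ifelse(cluster == classical_cluster, "classical", "basal-like"),
    cluster_index = cluster
  )
  pcs <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(pcs) <- paste0("pc", seq_len(n_pcs))
  dplyr::bind_cols(out, pcs)
}

#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression and the score of a set is
#' the sum over the ranked list of the difference between the in-set
#' weighted empirical CDF (weights `rank^alpha`) and the out-of-set
#' unweighted empirical CDF. Scores are rank-based, hence invariant to any
#' strictly monotone transform of one sample's expression.
#'
#' @param values Genes x samples expression matrix with gene rownames.
#' @param gene_sets Named list of gene ID vectors.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize If `TRUE`, scores are scaled by the range of all scores
#'   across samples and sets (cohort min-max style).
#' @return Tibble: `sample_id`, `set_name`, `score`, `n_genes_used`. Sets
#'   with no genes in the matrix are skipped with a message.
#' @export
ssgsea_scores <- function(values, gene_sets, alpha = 0.25,
                          normalize = FALSE) {
  if (is.null(rownames(values))) ck_abort("`values` must have gene rownames.")
  n_genes <- nrow(values)
  res <- list()
  for (set_name in names(gene_sets)) {
    genes <- intersect(unique(gene_sets[[set_name]]), rownames(values))
    if (length(genes) == 0) {
      rlang::inform(sprintf("gene set '%s' has no genes in the matrix; skipped.",
                            set_name))
      next
    }
    in_set <- rownames(values) %in% genes
    scores <- vapply(seq_len(ncol(values)), function(j) {
      x <- values[, j]
      if (length(unique(x)) == 1) {
        rlang::warn("all-tied expression; ranks defined by stable gene order.")
      }
      # rank 1 = lowest; ties broken by stable (first) order
      r <- rank(x, ties.method = "first")
      ord <- order(r, decreasing = TRUE)  # highest expression first
      ind <- in_set[ord]
      w <- r[ord]^alpha
      p_in <- cumsum(w * ind) / sum(w * ind)
      p_out <- cumsum(!ind) / (n_genes - sum(ind))
      sum(p_in - p_out)
    }, numeric(1))
    res[[set_name]] <- tibble::tibble(
      sample_id = colnames(values), set_name = set_name,
      score = scores, n_genes_used = length(genes)
    )
  }
  out <- dplyr::bind_rows(res)
  if (normalize && nrow(out) > 0) {
    rng <- range(out$score)
    if (diff(rng) > 0) out$score <- out$score / diff(rng)
  }
  out
}

#' Stratify scores at the cohort median
#'
#' High stratum is a score strictly above the median; values at or below
#' the median (including exact ties) are assigned to the low stratum.
#'
#' @param scores Tibble with a `score` column (and anything else, e.g.
#'   `sample_id`), or a bare numeric vector.
#' @return The input with an added `stratum` column (`"high"`/`"low"`), or a
#'   character vector if `scores` was numeric.
#' @export
stratify_by_median <- function(scores) {
  if (is.numeric(scores)) {
    if (length(scores) < 2) ck_abort("need at least two samples.")
    return(ifelse(scores > median(scores), "high", "low"))
  }
  assert_cols(scores, "score", "scores")
  if (nrow(scores) < 2) ck_abort("need at least two samples.")
  dplyr::mutate(scores,
                stratum = ifelse(.data$score > median(.data$score),
                                 "high", "low"))
}

#' Collapse sample-level subtype labels to patient level
#'
#' Patients with multiple biopsies keep the label of their earliest sample
#' (first-biopsy rule) for survival joins.
#'
#' @param assignments Tibble from [classify_molecular_subtype()] plus
#'   `patient_id` and an ordering column `sample_order` (e.g. biopsy day).
#' @return Tibble with one row per patient.
#' @export
collapse_to_patient <- function(assignments) {
  assert_cols(assignments, c("patient_id", "sample_order"), "assignments")
  assignments |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$sample_order, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}
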