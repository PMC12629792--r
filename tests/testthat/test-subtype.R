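test_that("z-score transform centers and scales genes with sample SD", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_warning(z <- zscore_transform(m), "zero-variance")
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_false("g2" %in% rownames(z))
  # idempotence on already z-scored input
  expect_equal(zscore_transform(z), z, tolerance = 1e-12)
})

test_that("subtype classification recovers separable structure", {
  labels <- rep(c("classical", "basal-like"), 50)
  cla <- sprintf("CLA%02d", 1:25)
  bas <- sprintf("BAS%02d", 1:25)
  ex <- simulate_expression_matrix(100, labels, cla, bas, effect_size = 3,
                                   seed = 12)
  out <- classify_molecular_subtype(ex$values, cla, bas, seed = 1)
  expect_gte(mean(out$subtype == labels), 0.95)
  expect_equal(sort(unique(out$cluster_index)), c(1L, 2L))
})

test_that("classification is deterministic and permutation-invariant", {
  labels <- rep(c("classical", "basal-like"), 20)
  cla <- sprintf("CLA%02d", 1:10)
  bas <- sprintf("BAS%02d", 1:10)
  ex <- simulate_expression_matrix(40, labels, cla, bas, seed = 3,
                                   n_background = 50)
  a <- classify_molecular_subtype(ex$values, cla, bas, seed = 5)
  b <- classify_molecular_subtype(ex$values, cla, bas, seed = 5)
  expect_identical(a, b)
  perm <- sample(nrow(ex$values))
  c_ <- classify_molecular_subtype(ex$values[perm, ], cla, bas, seed = 5)
  expect_equal(c_$subtype, a$subtype)
  # duplicated samples receive identical labels
  dup <- cbind(ex$values, ex$values)
  colnames(dup) <- make.unique(colnames(dup))
  d <- classify_molecular_subtype(dup, cla, bas, seed = 5)
  expect_equal(d$subtype[1:40], d$subtype[41:80])
})

test_that("k-means on few samples equals the exhaustive best-SSE partition", {
  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(rnorm(12), nrow = 6)
    labs <- kmeans_cluster_samples(x, k = 2, seed = rep)
    ref <- best_sse_2partition(x)
    sse <- sum(vapply(1:2, function(g) {
      pts <- x[labs == g, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    expect_equal(sse, ref$sse, tolerance = 1e-9)
  }
})

test_that("ssGSEA matches the direct running-sum oracle", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(rnorm(20 * 4), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:4)))
    genes <- sample(rownames(m), sample(3:8, 1))
    got <- ssgsea_scores(m, list(S = genes))
    for (j in 1:4) {
      expect_equal(got$score[j],
                   ssgsea_oracle_one(m[, j], genes), tolerance = 1e-9)
    }
  }
})

test_that("ssGSEA is maximal when set genes occupy the top ranks", {
  x <- setNames(20:1, sprintf("g%02d", 1:20))
  m <- cbind(s1 = x)
  top <- ssgsea_scores(m, list(S = sprintf("g%02d", 1:5)))$score
  set.seed(4)
  for (rep in 1:20) {
    other <- ssgsea_scores(m, list(S = sample(names(x), 5)))$score
    expect_lte(other, top)
  }
})

test_that("ssGSEA is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  genes <- sample(names(x), 6)
  a <- ssgsea_scores(cbind(s = x), list(S = genes))$score
  b <- ssgsea_scores(cbind(s = exp(2 * x) + 5), list(S = genes))$score
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("five-gene toy case matches a hand ECDF computation", {
  # expression s1: g1=5 > g2=4 > g3=3 > g4=2 > g5=1; set = {g1, g3}
  x <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  alpha <- 0.25
  w <- c(5, 3)^alpha            # ranks of g1, g3 (rank 5 = highest)
  p_in <- cumsum(c(w[1], 0, w[2], 0, 0)) / sum(w)
  p_out <- cumsum(c(0, 1, 0, 1, 1)) / 3
  hand <- sum(p_in - p_out)
  got <- ssgsea_scores(cbind(s = x), list(S = c("g1", "g3")))$score
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("median stratification is strict", {
  s <- tibble::tibble(sample_id = letters[1:4], score = c(1, 2, 3, 4))
  expect_equal(stratify_by_median(s)$stratum, c("low", "low", "high", "high"))
  expect_true(all(stratify_by_median(rep(2, 5)) == "low"))
  expect_equal(stratify_by_median(c(1, 2, 3)), c("low", "low", "high"))
})

test_that("patient collapse keeps the earliest biopsy", {
  df <- tibble::tibble(patient_id = c("A", "A", "B"),
                       sample_order = c(2, 1, 1),
                       subtype = c("basal-like", "classical", "classical"))
  out <- collapse_to_patient(df)
  expect_equal(out$subtype[out$patient_id == "A"], "classical")
  expect_equal(nrow(out), 2)
})
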