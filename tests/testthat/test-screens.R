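test_that("Fisher's exact test follows the exact-probability convention", {
  out <- fisher_exact_test(matrix(c(17, 3, 9, 9), 2, byrow = TRUE))
  expect_equal(out$p, 0.0354, tolerance = 1e-2)
  balanced <- fisher_exact_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(balanced$p, 1)
  zero_margin <- fisher_exact_test(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_equal(zero_margin$p, 1)
  expect_true(is.na(zero_margin$odds_ratio))
  expect_error(fisher_exact_test(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(14)
  for (rep in 1:50) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- fisher_exact_test(tab)$p
    ref <- fisher_p_enum(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("the Fisher screen drops rare features and adjusts per endpoint", {
  set.seed(5)
  n <- 40
  features <- data.frame(
    common = rbinom(n, 1, 0.5),
    rare = c(1, 1, rep(0, n - 2)),       # altered in only 2 samples
    predictive = rep(c(1, 0), each = n / 2)
  )
  endpoints <- data.frame(resp = rep(c("yes", "no"), each = n / 2))
  out <- fisher_screen(features, endpoints)
  expect_equal(attr(out, "excluded"), "rare")
  expect_false("rare" %in% out$feature)
  # a perfectly predictive feature achieves the extremal p for its margins
  p_pred <- out$p[out$feature == "predictive"]
  expect_equal(p_pred, fisher_p_enum(20, 0, 0, 20), tolerance = 1e-12)
  expect_true(all(out$q >= out$p - 1e-12))
  expect_warning(
    fisher_screen(features["common"], data.frame(flat = rep("a", n))),
    "constant"
  )
})

test_that("BH adjustment matches the naive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(77)
  for (rep in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bh_naive(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH output is monotone in sorted p and order-invariant", {
  set.seed(78)
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
})

test_that("the confounding screen routes tests by covariate type", {
  set.seed(9)
  n <- 16
  cov <- data.frame(
    age = rnorm(n, 60, 8),
    dup_age = NA,
    sex = rep(c("F", "M"), n / 2),
    site = rep(c("a", "a", "a", "c"), n / 4)  # rare level: expected < 5
  )
  cov$dup_age <- cov$age  # numeric pair with exact dependence
  out <- confounding_screen(cov)
  self <- out[out$var1 == "age" & out$var2 == "dup_age", ]
  expect_equal(self$statistic, 1, tolerance = 1e-12)
  expect_equal(self$test, "pearson")
  expect_equal(out$test[out$var1 == "sex" & out$var2 == "site"], "fisher")
  expect_true(all(out$test[out$var1 %in% c("age", "dup_age") &
                             out$var2 %in% c("sex", "site")] == "anova"))
  expect_true(all(out$q >= 0 & out$q <= 1))
})

test_that("categorical pairs with large expected counts use chi-square", {
  set.seed(10)
  n <- 400
  cov <- data.frame(a = rep(c("x", "y"), n / 2),
                    b = sample(c("u", "v"), n, replace = TRUE))
  out <- confounding_screen(cov)
  expect_equal(out$test, "chisq")
  expect_warning(confounding_screen(data.frame(a = rep("x", 10),
                                               b = rnorm(10))),
                 "single level")
})
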