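test_that("%MAF is the mutant fraction of total copies, as a percentage", {
  expect_equal(compute_maf(2, 100), 2)
  expect_equal(compute_maf(0, 500), 0)
  expect_equal(compute_maf(500, 500), 100)
  expect_error(compute_maf(5, 0), "total_conc")
  expect_error(compute_maf(10, 5), "exceeds")
})

test_that("standardization divides by the baseline anchor", {
  maf <- tibble::tibble(day = c(0, 28, 56), maf_pct = c(10, 1, 0.5))
  expect_equal(standardize_series(maf, "maf")$maf_rel, c(1, 0.1, 0.05))
  sld <- tibble::tibble(day = c(0, 56), sld_mm = c(50, 35))
  expect_equal(standardize_series(sld, "sld")$sld_rel_pct, c(100, 70))
  zero <- tibble::tibble(day = c(0, 28), maf_pct = c(0, 1))
  expect_error(standardize_series(zero, "maf"), class = "ctkinetics_exclusion")
})

test_that("baseline anchor is the latest pre-dose measurement", {
  maf <- tibble::tibble(day = c(-14, -3, 28), maf_pct = c(4, 8, 2))
  expect_equal(standardize_series(maf, "maf")$maf_rel, c(0.5, 1, 0.25))
  late <- tibble::tibble(day = c(7, 28), maf_pct = c(4, 2))
  expect_warning(out <- standardize_series(late, "maf"), "baseline")
  expect_equal(out$maf_rel, c(1, 0.5))
})

test_that("nearest-neighbor matching breaks ties toward the earlier measurement", {
  sld <- tibble::tibble(day = c(0, 56), sld_mm = c(50, 40))
  maf <- tibble::tibble(day = c(0, 49, 63), maf_pct = c(5, 2, 1))
  pairs <- match_timepoints(sld, maf)
  expect_equal(pairs$maf_day, c(0, 49))
  expect_equal(pairs$gap_days, c(0, 7))
})

test_that("matching drops pairs beyond the gap limit and reports gaps", {
  sld <- tibble::tibble(day = c(0, 56), sld_mm = c(50, 40))
  maf <- tibble::tibble(day = c(0, 49), maf_pct = c(5, 2))
  kept <- match_timepoints(sld, maf, max_gap_days = 21)
  expect_equal(nrow(kept), 2)
  dropped <- match_timepoints(sld, maf, max_gap_days = 5)
  expect_equal(nrow(dropped), 1)
  same <- match_timepoints(sld, tibble::tibble(day = c(0, 56),
                                               maf_pct = c(5, 2)))
  expect_true(all(same$gap_days == 0))
  gs <- gap_summary(kept)
  expect_equal(gs$mean_gap_days, 3.5)
  expect_equal(gs$n_pairs, 2)
})

test_that("noiseless exponential data are recovered exactly", {
  sld <- c(20, 40, 60, 80)
  pairs <- tibble::tibble(sld_mm = sld, maf_pct = 10^(-2 + 0.02 * sld))
  fit <- fit_patient_exponential(pairs)
  expect_equal(fit$beta, 0.02, tolerance = 1e-9)
  expect_equal(fit$alpha, -2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("patients with fewer than three usable points are excluded", {
  two <- tibble::tibble(sld_mm = c(20, 40), maf_pct = c(1, 2))
  expect_error(fit_patient_exponential(two), class = "ctkinetics_exclusion")
  # zeros do not count as usable points without a pseudo-count
  zeros <- tibble::tibble(sld_mm = c(20, 40, 60), maf_pct = c(1, 2, 0))
  expect_error(fit_patient_exponential(zeros),
               class = "ctkinetics_exclusion")
  expect_equal(fit_patient_exponential(zeros, pseudo_maf = 0.01)$n_points, 3)
})

test_that("fits agree with the normal-equations oracle on random instances", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    sld <- runif(n, 10, 150)
    maf <- 10^(rnorm(1, -2, 0.5) + rnorm(1, 0.03, 0.01) * sld +
                 rnorm(n, 0, 0.3))
    fit <- fit_patient_exponential(tibble::tibble(sld_mm = sld,
                                                  maf_pct = maf))
    ref <- ols_oracle(sld, log10(maf))
    expect_equal(fit$alpha, ref[1], tolerance = 1e-9)
    expect_equal(fit$beta, ref[2], tolerance = 1e-9)
  }
})

test_that("noisy fits recover the slope within three standard errors", {
  set.seed(55)
  sld <- runif(60, 10, 120)
  maf <- 10^(-2 + 0.025 * sld + rnorm(60, 0, 0.15))
  fit <- fit_patient_exponential(tibble::tibble(sld_mm = sld, maf_pct = maf))
  se <- summary(lm(log10(maf) ~ sld))$coefficients[2, 2]
  expect_lt(abs(fit$beta - 0.025), 3 * se)
})

test_that("SLD reductions translate to %MAF reductions via the fitted slope", {
  fits <- tibble::tibble(patient_id = c("A", "B"), beta = c(0.02, 0))
  baselines <- tibble::tibble(patient_id = c("A", "B"), sld0 = c(50, 60))
  out <- translate_sld_threshold(fits, baselines)
  expect_equal(out$per_patient$maf_reduction_pct[1],
               100 * (1 - 10^(-0.3)), tolerance = 1e-9)
  expect_equal(out$per_patient$maf_reduction_pct[2], 0)
  # missing baseline is skipped, not an error
  short <- suppressMessages(
    translate_sld_threshold(fits, baselines[1, ])
  )
  expect_equal(short$skipped, "B")
  expect_equal(nrow(short$per_patient), 1)
})

test_that("correlation matches the closed-form Pearson oracle", {
  sld <- c(20, 35, 50, 80, 110)
  exact <- tibble::tibble(sld_mm = sld, maf_pct = 10^(-2 + 0.02 * sld))
  out <- correlate_maf_sld(exact)
  expect_equal(out$r[out$scale == "absolute"], 1, tolerance = 1e-9)
  anti <- tibble::tibble(sld_mm = sld, maf_pct = 10^(2 - 0.02 * sld))
  expect_equal(correlate_maf_sld(anti)$r[1], -1, tolerance = 1e-9)

  set.seed(7)
  noisy <- tibble::tibble(sld_mm = runif(30, 10, 100))
  noisy$maf_pct <- 10^(-2 + 0.02 * noisy$sld_mm + rnorm(30, 0, 0.4))
  r_pkg <- correlate_maf_sld(noisy)$r[1]
  x <- noisy$sld_mm; y <- log10(noisy$maf_pct)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_pkg, r_ref, tolerance = 1e-12)
  expect_error(correlate_maf_sld(exact[1:2, ]), "three")
})
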