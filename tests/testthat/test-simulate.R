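test_that("identical seed and config give identical cohorts", {
  cfg <- cohort_config(n_patients = 15, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (nm in c("patients", "sld", "ctdna", "immune", "survival", "truth")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  expect_identical(a$expression$values, b$expression$values)
  c2 <- simulate_cohort(cohort_config(n_patients = 15, seed = 43))
  expect_false(identical(a$ctdna, c2$ctdna))
})

test_that("responder count is binomial around n * response_prob", {
  co <- simulate_cohort(cohort_config(n_patients = 100, response_prob = 0.4,
                                      seed = 11))
  n_resp <- sum(co$truth$is_responder)
  expect_lt(abs(n_resp - 40), 3 * sqrt(100 * 0.4 * 0.6))
})

test_that("zero noise makes log10(%MAF) exactly affine in SLD", {
  cfg <- cohort_config(
    n_patients = 20, maf_noise_sd = 0, detection_floor_pct = 0,
    genotype_probs = c(G12D = 0.5, G12V = 0.5, G12R = 0, WT = 0), seed = 3
  )
  co <- simulate_cohort(cfg)
  for (id in unique(co$ctdna$patient_id)) {
    ct <- co$ctdna[co$ctdna$patient_id == id, ]
    tr <- co$truth[co$truth$patient_id == id, ]
    lat <- simulate_sld_trajectory(tr$baseline_sld, tr$rate,
                                   ct$day)
    expect_equal(log10(ct$maf_pct), tr$intercept + tr$true_beta * lat$sld_mm,
                 tolerance = 1e-12)
  }
})

test_that("SLD trajectories follow the exponential closed form", {
  tr <- simulate_sld_trajectory(50, -0.01, c(0, 30))
  expect_equal(tr$sld_mm[2], 50 * exp(-0.3), tolerance = 1e-12)
  flat <- simulate_sld_trajectory(40, 0, c(0, 28, 56))
  expect_true(all(flat$sld_mm == 40))
  up <- simulate_sld_trajectory(40, 0.005, seq(0, 200, 20))
  expect_true(all(diff(up$sld_mm) > 0))
  expect_error(simulate_sld_trajectory(-5, 0.01, c(0, 10)), "baseline")
  expect_error(simulate_sld_trajectory(50, 0.01, c(-5, 10)), "nonnegative")
})

test_that("two-phase trajectories decay then regrow", {
  tr <- simulate_sld_trajectory(50, -0.01, seq(0, 280, 28), two_phase = TRUE,
                                switch_day = 140, regrowth_rate = 0.004)
  expect_true(all(diff(tr$sld_mm[tr$day <= 140]) < 0))
  expect_true(all(diff(tr$sld_mm[tr$day >= 140]) > 0))
})

test_that("ctDNA coupling honors closed form and detection floor", {
  sld <- tibble::tibble(day = 0, sld_mm = 50)
  out <- simulate_ctdna_from_sld(sld, 0.02, -2, noise_sd = 0)
  expect_equal(out$maf_pct, 0.1, tolerance = 1e-12)
  floored <- simulate_ctdna_from_sld(sld, 0.02, -4, noise_sd = 0,
                                     detection_floor = 0.05)
  expect_equal(floored$maf_pct, 0)
  expect_false(floored$detected)
  expect_error(simulate_ctdna_from_sld(sld, 0.02, -2, noise_sd = -1), "noise")
})

test_that("OLS on noisy coupled data recovers the generative slope", {
  sld <- tibble::tibble(day = seq_len(400), sld_mm = runif(400, 10, 120))
  out <- simulate_ctdna_from_sld(sld, 0.03, -2.5, noise_sd = 0.1, seed = 7)
  fit <- lm(log10(out$maf_pct) ~ sld$sld_mm)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(coef(fit)[2] - 0.03), 3 * se)
})

test_that("immune panel medians sit near 1 without effects and shift with them", {
  pats <- tibble::tibble(patient_id = sprintf("P%02d", 1:40),
                         is_responder = rep(c(TRUE, FALSE), 20))
  null_panel <- simulate_immune_panel(pats, c("Ki67+ T cells", "B cells"),
                                      seed = 5)
  fc <- fold_change_table(null_panel, "C1D1", "C1D2")
  expect_lt(abs(median(fc$fc) - 1), 0.1)
  eff <- simulate_immune_panel(
    pats, c("Ki67+ T cells", "B cells"),
    effect_map = tibble::tibble(population = "Ki67+ T cells",
                                stratum = "responder", fold = 2),
    seed = 5
  )
  fc2 <- dplyr::left_join(fold_change_table(eff, "C1D1", "C1D2"), pats,
                          by = "patient_id")
  p_by_pop <- vapply(split(fc2, fc2$population), function(d) {
    normality_gated_compare(d$fc[d$is_responder], d$fc[!d$is_responder])$p
  }, numeric(1))
  expect_lt(p_by_pop[["Ki67+ T cells"]], 0.01)
  expect_gt(p_by_pop[["B cells"]], 0.05)
})

test_that("survival respects the PFS <= OS and censoring contracts", {
  truth <- tibble::tibble(patient_id = sprintf("P%02d", 1:50),
                          is_responder = rep(c(TRUE, FALSE), 25))
  sv <- simulate_survival(truth, seed = 9)
  expect_true(all(sv$pfs_days <= sv$os_days))
  degenerate <- simulate_survival(truth, admin_censor_day = 0, seed = 9)
  expect_true(all(degenerate$os_days == 0))
  expect_true(all(degenerate$os_event == 0))
  expect_error(simulate_survival(truth, os_hazard = -1), "positive")
})

test_that("config validation rejects bad probability vectors and schedules", {
  expect_error(cohort_config(genotype_probs = c(G12D = 0.5, G12V = 0.5,
                                                G12R = 0.5, WT = 0)),
               "sum to 1")
  expect_error(cohort_config(visit_days = numeric(0)), "nonempty")
  expect_error(cohort_config(visit_days = c(0, 10, 5)), "increasing")
  expect_error(cohort_config(response_prob = 1.5), "probability")
})
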