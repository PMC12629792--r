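series <- function(days, mafs) tibble::tibble(day = days, maf_pct = mafs)

test_that("clearance threshold is the wild-type mean plus three SDs", {
  expect_equal(compute_clearance_threshold(c(0, 0, 0)), 0)
  expect_equal(compute_clearance_threshold(c(0.01, 0.02, 0.03)), 0.05)
  expect_equal(compute_clearance_threshold(c(0.7, 0.7, 0.7)), 0.7)
  expect_error(compute_clearance_threshold(0.1), "at least two")
  # threshold never below the mean; equality iff sd = 0
  set.seed(3)
  x <- runif(20)
  expect_gte(compute_clearance_threshold(x), mean(x))
})

test_that("clearance is called inside the window against the threshold", {
  cfg <- molecular_call_config(clearance_threshold = 0.05)
  hit <- call_clearance(series(c(0, 56, 100), c(5, 1, 0)), cfg)
  expect_true(hit$cleared)
  expect_equal(hit$first_clearance_day, 100)
  late <- call_clearance(series(c(0, 300), c(5, 0)), cfg)
  expect_false(late$cleared)
  not_eval <- call_clearance(series(c(0, 56), c(0, 0)), cfg)
  expect_false(not_eval$evaluable)
})

test_that("molecular response needs >= 90% reduction within 70 days", {
  deep_early <- call_mresponse(series(c(0, 42), c(20, 1.5)))
  expect_true(deep_early$mresponse)
  expect_equal(deep_early$mresponse_day, 42)
  deep_late <- call_mresponse(series(c(0, 84), c(20, 1)))
  expect_false(deep_late$mresponse)
  shallow <- call_mresponse(series(c(0, 35), c(100, 11)))
  expect_false(shallow$mresponse)  # 89% misses the 90% bar
  no_base <- call_mresponse(series(c(0, 35), c(0, 1)))
  expect_false(no_base$evaluable)
})

test_that("molecular progression compares against any previous measurement", {
  s <- series(c(0, 30, 60), c(1.0, 0.5, 0.56))
  rel <- call_mprogression(s)
  expect_true(rel$mprogression)  # +12% over the day-30 value
  expect_equal(rel$mprogression_day, 60)
  abs_mode <- call_mprogression(
    s, molecular_call_config(mprogression_mode = "absolute_points")
  )
  expect_false(abs_mode$mprogression)  # +0.06 points < 10 points
  late <- call_mprogression(series(c(0, 250), c(1, 2)))
  expect_false(late$mprogression)  # increase only beyond day 225
  single <- call_mprogression(series(0, 1))
  expect_false(single$evaluable)
})

test_that("call monotonicity: relaxing the response bar never unmakes a call", {
  set.seed(21)
  for (i in 1:25) {
    s <- series(c(0, 14, 28, 56, 70), c(10, 10 * 10^(-runif(4, 0, 2))))
    strict <- call_mresponse(s, molecular_call_config(mresponse_reduction = 0.95))
    loose <- call_mresponse(s, molecular_call_config(mresponse_reduction = 0.80))
    if (strict$mresponse) expect_true(loose$mresponse)
  }
})

test_that("cohort-level calling is idempotent and threshold-aware", {
  co <- simulate_cohort(cohort_config(n_patients = 25, seed = 17))
  ctdna <- dplyr::left_join(co$ctdna,
                            co$patients[, c("patient_id", "genotype")],
                            by = "patient_id")
  calls1 <- call_molecular(ctdna)
  calls2 <- call_molecular(ctdna)
  expect_identical(tidy(calls1), tidy(calls2))
  # threshold derived from WT patients is positive and excludes them
  expect_gt(attr(calls1, "config")$clearance_threshold, 0)
  expect_false(any(calls1$patient_id %in%
                     co$patients$patient_id[co$patients$genotype == "WT"]))
  g <- glance(calls1)
  expect_equal(g$n_patients, sum(co$patients$genotype != "WT"))
})

test_that("call config validation rejects out-of-range thresholds", {
  expect_error(molecular_call_config(mresponse_reduction = 0), "0, 1")
  expect_error(molecular_call_config(mresponse_window_days = -1), "windows")
  expect_error(molecular_call_config(clearance_threshold = -0.1), ">= 0")
})

test_that("call configs load from YAML with defaults for unset fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mresponse_reduction: 0.85", "clearance_threshold: 0.04"),
             path)
  cfg <- read_call_config(path)
  expect_equal(cfg$mresponse_reduction, 0.85)
  expect_equal(cfg$clearance_threshold, 0.04)
  expect_equal(cfg$mresponse_window_days, 70)
  writeLines("not_a_field: 1", path)
  expect_error(read_call_config(path), "unknown config field")
})
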