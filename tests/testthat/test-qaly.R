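test_that("tariff scoring: full health, toy decrements, validation", {
  tt <- toy_tariff()
  expect_equal(score_profile(c(1, 1, 1, 1, 1), tt), 1.0)
  expect_equal(score_profile(c(2, 1, 1, 1, 1), tt), 0.95)
  expect_equal(score_profile(c(5, 5, 5, 5, 5), tt), 0.0)
  expect_true(is.na(score_profile(c(1, NA, 1, 1, 1), tt)))
  expect_error(score_profile(c(0, 1, 1, 1, 1), tt), "1..5")
  expect_error(score_profile(c(6, 1, 1, 1, 1), tt), "1..5")
  # a tariff must value 11111 at 1
  bad <- matrix(0.1, 5, 5)
  expect_error(eq5d_tariff(bad), "11111")
})

test_that("tariff files round-trip through both representations", {
  path <- system.file("extdata", "tariff_toy.csv", package = "urocea")
  tt <- read_tariff(path)
  expect_equal(score_profile(c(3, 2, 1, 1, 1), tt), 1 - 0.1 - 0.05)
  # full-lookup variant scores identically
  states <- expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5)
  keys <- apply(states[, 5:1], 1, paste0, collapse = "")
  vals <- 1 - 0.05 * rowSums(states - 1)
  lk <- eq5d_tariff_lookup(setNames(vals, keys))
  expect_equal(score_profile(c(3, 2, 1, 1, 1), lk),
               score_profile(c(3, 2, 1, 1, 1), tt))
})

test_that("AUC QALYs: closed forms, linearity, collinear-point invariance", {
  expect_equal(qaly_auc(c(0, 730.5), c(1, 1)), 2.0)
  expect_equal(qaly_auc(c(0, 365.25), c(0.8, 0.6)), 0.7)
  expect_equal(qaly_auc(c(0, 100, 500), c(0, 0, 0)), 0)
  expect_error(qaly_auc(0, 1), "at least two")
  expect_error(qaly_auc(c(0, 0), c(1, 1)), "strictly increasing")

  d <- c(0, 91, 183, 365, 730)
  u <- c(0.7, 0.8, 0.85, 0.9, 0.8)
  expect_equal(qaly_auc(d, u), trapz_by_hand(d, u) / 365.25)
  # linear in utilities
  expect_equal(qaly_auc(d, u / 2), qaly_auc(d, u) / 2)
  # inserting a collinear midpoint leaves the area unchanged
  d2 <- c(0, 91, 137, 183, 365, 730)
  u2 <- c(0.7, 0.8, stats::approx(d, u, 137)$y, 0.85, 0.9, 0.8)
  expect_equal(qaly_auc(d2, u2), qaly_auc(d, u))
})

test_that("rescaling is the stated multiplication and nothing else", {
  expect_equal(rescale_qaly(1.5, 730, 730), 1.5)
  expect_equal(round(rescale_qaly(1.5, 760, 730), 4), 1.4408)
  expect_equal(rescale_qaly(0, 512), 0)
  expect_error(rescale_qaly(1, 0), "positive")
})

test_that("discounted AUC: rate zero identity and year-boundary closed form", {
  d <- c(0, 91, 183, 365, 730)
  u <- c(0.7, 0.8, 0.85, 0.9, 0.8)
  expect_equal(discount_qaly_series(d, u, rate = 0), qaly_auc(d, u))
  # constant utility 1 over exactly two years: 1 + 1/1.035
  two_years <- discount_qaly_series(c(0, 730.5), c(1, 1), rate = 0.035)
  expect_equal(round(two_years, 4), 1.9662)
  expect_equal(two_years, 1 + 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_qaly_series(c(0, 400), c(0, 0)), 0)
  expect_error(discount_qaly_series(c(0, 10), c(1, 1), rate = -0.1),
               "non-negative")
})

test_that("complete-case rules follow the three rule sets", {
  trial <- simulate_trial(no_noise_config(n_per_arm = 2), compute_truth = FALSE)
  # patient 1: pretend no surgery, keep only randomisation-anchored points
  trial$patients$had_index_surgery[1] <- FALSE
  keep1 <- c("baseline", "m18_post_rand", "m24_post_rand")
  blank <- function(obs, id, tps) {
    i <- obs$id == id & obs$timepoint %in% tps
    for (d in eq5d_dimensions()) obs[[d]][i] <- NA_integer_
    obs
  }
  obs <- trial$observations
  obs <- blank(obs, 1L, setdiff(eq5d_timepoints(), keep1))
  # patient 2: baseline + 24m post-rand but no mid-range point
  obs <- blank(obs, 2L, c("m3_post_surgery", "m6_post_surgery",
                          "m9_post_surgery", "m12_post_surgery",
                          "m18_post_rand"))
  # patient 3: pre-surgery, 6m post-surgery, 24m post-surgery only
  obs <- blank(obs, 3L, setdiff(eq5d_timepoints(),
                                c("pre_surgery", "m6_post_surgery",
                                  "m24_post_surgery")))
  trial$observations <- obs

  cc_rand <- is_complete_case(trial, "post_randomisation")
  expect_true(cc_rand$complete_case[1])   # no-surgery rule satisfied
  expect_false(cc_rand$complete_case[2])  # fails the mid-range requirement
  expect_true(cc_rand$complete_case[4])   # untouched patient

  cc_surg <- is_complete_case(trial, "post_surgery")
  expect_true(cc_surg$complete_case[3])   # third rule set satisfied
  expect_true(cc_surg$complete_case[1])   # no-surgery patients use rule one
})

test_that("per-patient QALYs integrate scored series over the right window", {
  trial <- simulate_trial(no_noise_config(n_per_arm = 3), compute_truth = FALSE)
  q <- compute_qalys(trial)
  # constant utility 0.85 over 760 days from randomisation
  expect_equal(unique(round(q$qaly, 10)),
               round(0.85 * 760 / 365.25, 10))
  expect_true(all(q$complete_case))
  # post-surgery window: anchored at the pre-surgery assessment
  qs <- compute_qalys(trial, analysis = "post_surgery")
  span <- 760 - (40 - 1) # capped end minus anchor day
  expect_equal(unique(round(qs$qaly, 10)),
               round(0.85 * span / 365.25, 10))
  # rescaled variant multiplies by 730/span
  qr <- compute_qalys(trial, analysis = "post_surgery", rescale = TRUE)
  expect_equal(unique(round(qr$qaly, 10)),
               round(0.85 * 730 / 365.25, 10))
})
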