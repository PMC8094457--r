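test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(stratum_prob = 1.5), "stratum_prob")
  expect_error(sim_config(crossover_prob = -0.1), "crossover_prob")
  expect_error(sim_config(n_per_arm = 0), "n_per_arm")

  cfg <- sim_config()
  cfg$utility_params$between_sd <- -1
  expect_error(simulate_trial(cfg, compute_truth = FALSE), "between_sd")

  cfg <- sim_config()
  cfg$recurrence_hazard[["urethrotomy"]] <- 1.2
  expect_error(simulate_trial(cfg, compute_truth = FALSE), "recurrence_hazard")

  cfg <- sim_config()
  cfg$utility_params$trajectory$urethroplasty[["baseline"]] <- 1.4
  expect_error(simulate_trial(cfg, compute_truth = FALSE), "trajectory")
})

test_that("identical seeds reproduce identical datasets, different seeds differ", {
  cfg <- sim_config(n_per_arm = 25)
  a <- simulate_trial(cfg, seed = 7, compute_truth = FALSE)
  b <- simulate_trial(cfg, seed = 7, compute_truth = FALSE)
  c <- simulate_trial(cfg, seed = 8, compute_truth = FALSE)
  for (el in c("patients", "observations", "resources", "oop",
               "reinterventions")) {
    expect_identical(a[[el]], b[[el]])
  }
  expect_false(identical(a$observations, c$observations))
})

test_that("trial structure obeys its invariants", {
  trial <- simulate_trial(sim_config(n_per_arm = 60, seed = 11),
                          compute_truth = FALSE)
  p <- trial$patients
  expect_equal(unname(table(p$arm_allocated)), c(60L, 60L),
               ignore_attr = TRUE)
  expect_true(all(trial$observations$day >= 0 &
                    trial$observations$day <= 760))
  lv <- as.matrix(trial$observations[, eq5d_dimensions()])
  expect_true(all(is.na(lv) | (lv >= 1 & lv <= 5)))
  # re-interventions happen strictly after surgery
  ri <- dplyr::left_join(trial$reinterventions,
                         p[, c("id", "surgery_day")], by = "id")
  expect_true(all(ri$day > ri$surgery_day))
  expect_true(all(ri$day <= 760))
})

test_that("a noise-free configuration reproduces the trajectory means exactly", {
  trial <- simulate_trial(no_noise_config(n_per_arm = 4), compute_truth = FALSE)
  obs <- add_utilities(trial$observations, toy_tariff())
  expect_equal(nrow(obs), 8 * length(eq5d_timepoints()))
  expect_true(all(obs$utility == 0.85))
  expect_equal(nrow(trial$reinterventions), 0)
})

test_that("missingness honours exact rates 0 and 1 and the baseline guard", {
  trial <- simulate_trial(no_noise_config(n_per_arm = 10), compute_truth = FALSE)
  same <- apply_missingness(trial, rates = 0, seed = 1)
  expect_identical(same$observations, trial$observations)

  gone <- apply_missingness(trial, rates = 1, preserve_baseline = TRUE, seed = 1)
  obs <- add_utilities(gone$observations, toy_tariff())
  expect_true(all(is.na(obs$utility[obs$timepoint != "baseline"])))
  expect_true(all(!is.na(obs$utility[obs$timepoint == "baseline"])))

  expect_error(apply_missingness(trial, rates = 1.4), "rates")
})

test_that("empirical missing fraction matches the nominal rate", {
  trial <- simulate_trial(no_noise_config(n_per_arm = 500, seed = 5),
                          compute_truth = FALSE)
  miss <- apply_missingness(trial, rates = 0.3, preserve_baseline = TRUE,
                            seed = 99)
  obs <- add_utilities(miss$observations, toy_tariff()) |>
    dplyr::filter(timepoint != "baseline")
  n <- nrow(obs)
  expect_gt(n, 9000)
  frac <- mean(is.na(obs$utility))
  half_width <- 2.576 * sqrt(0.3 * 0.7 / n) # binomial 99% interval
  expect_lt(abs(frac - 0.3), half_width)
})

test_that("truth record is consistent with independent re-simulation", {
  cfg <- delta_config(n_per_arm = 50, delta_oop = 2000, seed = 3)
  cfg$n_truth <- 4000
  t1 <- compute_truth(cfg, seed = 1)
  t2 <- compute_truth(cfg, seed = 23456)
  # both estimates target the same expectation; the built-in increment is 2000
  big <- simulate_trial(cfg, seed = 2, compute_truth = FALSE)
  costs <- cost_patients(big)
  sd_cost <- sd(costs$cost_societal)
  mc_se <- sd_cost * sqrt(2 / 4000)
  expect_lt(abs(attr(t1, "delta_cost") - 2000), 3 * mc_se)
  expect_lt(abs(attr(t1, "delta_cost") - attr(t2, "delta_cost")),
            3 * sqrt(2) * mc_se)
  expect_equal(unname(t1$recurrence_prob_24m), c(0, 0))
})
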