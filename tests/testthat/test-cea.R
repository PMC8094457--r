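test_that("joint fit equals per-equation least squares on identical regressors", {
  for (s in 1:5) {
    fr <- random_frame(n_per_arm = 30, seed = s)
    fit <- sur_adjusted_increments(fr)
    ols_c <- lm(cost ~ I(arm == "urethroplasty") + I(stratum == "lt12m") +
                  baseline_utility, data = fr)
    ols_q <- lm(qaly ~ I(arm == "urethroplasty") + I(stratum == "lt12m") +
                  baseline_utility, data = fr)
    expect_equal(fit$delta_cost, unname(coef(ols_c)[2]), tolerance = 1e-8)
    expect_equal(fit$delta_qaly, unname(coef(ols_q)[2]), tolerance = 1e-8)
    # adjusted means differ by exactly the arm coefficient
    expect_equal(unname(diff(rev(fit$adjusted_means$cost))), fit$delta_cost,
                 tolerance = 1e-10)
  }
})

test_that("arm-only model returns raw arm mean differences", {
  fr <- random_frame(n_per_arm = 25, seed = 9)
  fit <- sur_adjusted_increments(fr, covariates = character(0))
  raw <- mean(fr$cost[fr$arm == "urethroplasty"]) -
    mean(fr$cost[fr$arm == "urethrotomy"])
  expect_equal(fit$delta_cost, raw, tolerance = 1e-10)
})

test_that("singular designs error naming the collinear column", {
  fr <- random_frame(n_per_arm = 10, seed = 2)
  fr$shadow <- 1 # collinear with the intercept
  expect_error(sur_adjusted_increments(fr, covariates = "shadow"), "shadow")
})

test_that("ICER classification covers dominance, division and the tie rule", {
  base <- classify_icer(2148, -0.01)
  expect_equal(base$label, "dominated") # comparator is 'Dominant'
  expect_equal(classify_icer(-100, 0.2)$label, "dominant")
  icer <- classify_icer(1500, 0.005)
  expect_equal(icer$label, "icer")
  expect_equal(icer$icer, 300000)
  tie <- classify_icer(100, 0)
  expect_equal(tie$label, "dominated")
  expect_true(tie$flagged)
  expect_equal(classify_icer(-100, 0)$label, "dominant")
  expect_error(classify_icer(NaN, 1), "finite")
})

test_that("bootstrap draws are reproducible and collapse when variance is zero", {
  fr <- random_frame(n_per_arm = 20, seed = 4)
  d1 <- bootstrap_ce(fr, B = 200, seed = 5)
  d2 <- bootstrap_ce(fr, B = 200, seed = 5)
  expect_identical(d1, d2)
  expect_warning(bootstrap_ce(fr, B = 50, seed = 1), "100")

  flat <- fr
  flat$cost <- 1000 + 500 * (flat$arm == "urethroplasty")
  flat$qaly <- 1.5
  d <- suppressWarnings(
    bootstrap_ce(flat, B = 100, seed = 1, covariates = character(0)))
  expect_true(all(abs(d$delta_cost - 500) < 1e-9))
  expect_true(all(abs(d$delta_qaly) < 1e-12))
})

test_that("CEAC probabilities follow the net-benefit definition and sum to 1", {
  d <- tibble::tibble(delta_cost = c(1000, 1000), delta_qaly = c(0.1, -0.1))
  cc <- ceac(d, lambda = c(0, 10000, 20000))
  p_int <- cc$probability[cc$strategy == "urethroplasty"]
  expect_equal(p_int, c(0, 0, 0.5)) # lambda 0: fraction with lower cost
  sums <- cc |>
    dplyr::summarise(s = sum(probability), .by = lambda)
  expect_true(all(sums$s == 1))

  good <- tibble::tibble(delta_cost = -runif(50, 1, 100),
                         delta_qaly = runif(50, 0.01, 0.2))
  cg <- ceac(good)
  expect_true(all(cg$probability[cg$strategy == "urethroplasty"] == 1))
  # monotone non-decreasing when every draw has positive QALY gain
  mono <- tibble::tibble(delta_cost = rnorm(200, 500, 400),
                         delta_qaly = runif(200, 0.001, 0.05))
  cm <- ceac(mono, lambda = seq(0, 50000, 5000))
  expect_true(all(diff(cm$probability[cm$strategy == "urethroplasty"]) >= 0))
  expect_error(ceac(d[0, ]), "empty")
})

test_that("with no missing data imputation is a no-op and MI equals complete case", {
  trial <- simulate_trial(no_noise_config(n_per_arm = 10), compute_truth = FALSE)
  imp <- impute_utilities(trial, m = 3, seed = 1)
  base <- add_utilities(trial$observations, toy_tariff())
  for (i in 1:3) {
    expect_equal(imp$completed[[i]]$utility, base$utility)
    expect_false(any(imp$completed[[i]]$imputed))
  }
  cc <- cea_within_trial(trial, B = 120, seed = 2,
                         covariates = "stratum")
  mi <- mi_cea(trial, m = 3, B = 120, seed = 3, covariates = "stratum")
  expect_equal(mi$pooled$estimate[mi$pooled$term == "delta_cost"],
               cc$fit$delta_cost, tolerance = 1e-12)
  expect_equal(mi$pooled$estimate[mi$pooled$term == "delta_qaly"],
               cc$fit$delta_qaly, tolerance = 1e-12)
})

test_that("PMM with a single available donor returns that donor's value", {
  cfg <- sim_config(n_per_arm = 4, seed = 6)
  cfg$missing_rate$rates[] <- 0
  cfg$no_surgery_prob <- 0
  trial <- simulate_trial(cfg, compute_truth = FALSE)
  obs <- trial$observations
  i <- which(obs$timepoint == "m6_post_surgery")
  expect_gte(length(i), 3)
  for (d in eq5d_dimensions()) obs[[d]][i[-1]] <- NA_integer_
  trial$observations <- obs
  donor_utility <- score_profile(
    as.matrix(obs[i[1], eq5d_dimensions()]), toy_tariff())
  imp <- impute_utilities(trial, m = 2, seed = 8, k = 1)
  for (s in 1:2) {
    filled <- imp$completed[[s]]
    expect_true(all(filled$utility[i[-1]] == donor_utility))
  }
})

test_that("Rubin pooling reproduces the hand formula and rejects m = 1", {
  pooled <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$se^2, 1 + 1.5 * 2) # W + (1 + 1/m) B = 4
  expect_true(pooled$conf.low < 2 && pooled$conf.high > 2)

  same <- pool_rubin(c(2, 2, 2), c(0.5, 0.7, 0.9))
  expect_equal(same$se^2, 0.7)
  expect_equal(same$df, Inf)

  expect_error(pool_rubin(1, 1), "at least two")
  expect_error(pool_rubin(c(1, 2), 1), "same length")
})

test_that("dominated results render 'Dominant' on the comparator row", {
  # dearer and less effective: force a QALY disadvantage for urethroplasty
  cfgd <- no_noise_config(n_per_arm = 8, delta_oop = 500)
  cfgd$utility_params$trajectory$urethroplasty[] <- 0.80
  trial <- simulate_trial(cfgd, compute_truth = FALSE)
  res <- cea_within_trial(trial, B = 120, seed = 4, covariates = "stratum")
  expect_equal(res$icer$label, "dominated")
  tab <- render_table3(list(base = res))
  expect_equal(tab$icer[tab$strategy == "urethrotomy"], "Dominant")
  expect_equal(tab$icer[tab$strategy == "urethroplasty"], "")
})
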