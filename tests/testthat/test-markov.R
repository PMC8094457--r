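test_that("transition matrices are row-stochastic with death applied first", {
  spec <- markov_spec(
    procedures = list(urethroplasty = list(procedure_cost = 4000, p_recur = 0.2),
                      urethrotomy = list(procedure_cost = 2000, p_recur = 0.2)),
    p_death = 0.01
  )
  m <- build_transition_matrix(spec, "urethroplasty")
  expect_equal(unname(m["symptom_free", ]), c(0.792, 0.198, 0.01))
  expect_equal(unname(rowSums(m)), c(1, 1, 1))
  expect_equal(unname(m["deceased", ]), c(0, 0, 1))

  # no recurrence, no death: symptom-free absorbing
  calm <- markov_spec(p_death = 0)
  calm$procedures$urethroplasty$p_recur <- 0
  m0 <- build_transition_matrix(calm, "urethroplasty")
  expect_equal(unname(m0["symptom_free", ]), c(1, 0, 0))

  # policy: always the other procedure at recurrence
  other <- markov_spec(recurrence_policy = "always_other")
  mo <- build_transition_matrix(other, "urethrotomy")
  expect_equal(attr(mo, "reintervention_mix"),
               c(urethrotomy = 0, urethroplasty = 1))
})

test_that("specification validation rejects out-of-range parameters", {
  expect_error(markov_spec(p_death = 1.3), "p_death")
  expect_error(markov_spec(u_symptom_free = 1.2), "utilities|exceed")
  expect_error(markov_spec(horizon = 10, cycle_length = 0.7), "whole number")
  bad <- markov_spec()
  bad$procedures$urethrotomy$p_recur <- -0.1
  expect_error(run_cohort(bad, "urethrotomy"), "p_recur")
})

test_that("full-health decade: 10 QALYs undiscounted, 8.6077 at 3.5%", {
  spec <- markov_spec(
    procedures = list(urethroplasty = list(procedure_cost = 0, p_recur = 0),
                      urethrotomy = list(procedure_cost = 0, p_recur = 0)),
    p_death = 0, u_symptom_free = 1, u_symptomatic = 1, followup_cost = 0,
    cycle_length = 1, horizon = 10,
    discount_rate_costs = 0, discount_rate_qalys = 0
  )
  run <- run_cohort(spec, "urethroplasty")
  expect_equal(run$qaly, 10.0, tolerance = 1e-12)
  expect_equal(run$qaly, run$qaly_undiscounted)

  spec$discount_rate_qalys <- 0.035
  disc <- run_cohort(spec, "urethroplasty")
  expect_equal(disc$qaly, sum(1.035^-(0:9)), tolerance = 1e-12)
  expect_equal(round(disc$qaly, 4), 8.6077)

  spec$u_symptom_free <- 0
  spec$u_symptomatic <- 0
  expect_equal(run_cohort(spec, "urethroplasty")$qaly, 0)
})

test_that("occupancy sums to one every cycle and traces accumulate", {
  run <- run_cohort(default_markov_spec(), "urethrotomy")
  tr <- run$trace
  expect_true(all(abs(tr$symptom_free + tr$symptomatic + tr$deceased - 1)
                  < 1e-12))
  expect_equal(nrow(tr), 20)
  expect_equal(max(tr$cum_cost_discounted), run$cost)
  expect_true(run$cost <= run$cost_undiscounted)
  expect_true(run$qaly <= run$qaly_undiscounted)
})

test_that("mortality-only model matches the closed-form discounted lifetime", {
  d <- 0.03
  spec <- markov_spec(
    procedures = list(urethroplasty = list(procedure_cost = 0, p_recur = 0),
                      urethrotomy = list(procedure_cost = 0, p_recur = 0)),
    p_death = d, u_symptom_free = 1, u_symptomatic = 1, followup_cost = 0,
    cycle_length = 0.5, horizon = 10, discount_rate_qalys = 0.035,
    discount_rate_costs = 0.035
  )
  run <- run_cohort(spec, "urethroplasty")
  t <- 0:19
  closed <- sum((1 - d)^t * 1.035^-(t * 0.5) * 0.5)
  expect_equal(run$qaly, closed, tolerance = 1e-12)
})

test_that("scenario table covers the four analyses with sensible directions", {
  spec <- default_markov_spec()
  scen <- run_scenarios(spec, received_spec = spec)
  expect_setequal(unique(scen$analysis),
                  c("base_case", "treatment_received", "always_same",
                    "always_other"))
  # identical parameters for both strategies: increments vanish
  sym <- markov_spec()
  sym$procedures$urethrotomy <- sym$procedures$urethroplasty
  res <- run_strategies(sym)
  expect_equal(res$delta_cost, 0, tolerance = 1e-12)
  expect_equal(res$delta_qaly, 0, tolerance = 1e-12)
  # dearer initial procedure with less recurrence: QALY gain non-negative
  adv <- markov_spec()
  adv$procedures$urethroplasty$p_recur <- 0.02
  adv$procedures$urethrotomy$p_recur <- 0.15
  res2 <- run_strategies(adv)
  expect_gte(res2$delta_qaly, 0)
})

test_that("beta moment matching and PSA degeneracy/reproducibility", {
  mm <- beta_moments(0.2, 0.05)
  expect_equal(round(unname(mm), 1), c(12.6, 50.4))
  expect_error(beta_moments(0.2, 0.5, "p_recur"), "p_recur")

  spec <- default_markov_spec()
  det <- run_strategies(spec)
  ps_spec <- default_psa_spec(spec)
  ps_spec$se <- 0
  degenerate <- psa(spec, ps_spec, n_draws = 5, seed = 1)
  expect_true(all(abs(degenerate$draws$delta_cost - det$delta_cost) < 1e-9))
  expect_true(all(abs(degenerate$draws$delta_qaly - det$delta_qaly) < 1e-9))

  p1 <- psa(spec, n_draws = 50, seed = 42)
  p2 <- psa(spec, n_draws = 50, seed = 42)
  expect_identical(p1$ceac, p2$ceac)
  sums <- p1$ceac |> dplyr::summarise(s = sum(probability), .by = lambda)
  expect_true(all(sums$s == 1))
})
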