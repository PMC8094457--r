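test_that("price-year adjustment: identity, zero, hand ratio, transitivity", {
  expect_equal(adjust_price_year(100, 2017, cpi_flat, 2017), 100)
  expect_equal(adjust_price_year(0, 2015, cpi_flat, 2017), 0)
  # 100 * 102.9 / 98.0
  expect_equal(round(adjust_price_year(100, 2015, cpi_flat, 2017), 1), 105.0)
  via_2016 <- adjust_price_year(
    adjust_price_year(250, 2015, cpi_flat, 2016), 2016, cpi_flat, 2017)
  expect_equal(via_2016, adjust_price_year(250, 2015, cpi_flat, 2017))
  expect_error(adjust_price_year(10, 2011, cpi_flat, 2017), "2011")
})

test_that("procedure micro-costing sums quantity times unit cost", {
  uc <- unit_costs_2017(c("theatre_minute", "bed_day"), c(10, 300))
  expect_equal(procedure_cost(tibble::tibble(item = character(0),
                                             quantity = numeric(0)),
                              uc, cpi_flat), 0)
  res <- tibble::tibble(item = c("theatre_minute", "bed_day"),
                        quantity = c(90, 1.34))
  expect_equal(procedure_cost(res, uc, cpi_flat), 1302.0)
  # homogeneity: doubling quantities doubles the cost
  res2 <- dplyr::mutate(res, quantity = quantity * 2)
  expect_equal(procedure_cost(res2, uc, cpi_flat),
               2 * procedure_cost(res, uc, cpi_flat))
  expect_error(
    procedure_cost(tibble::tibble(item = "robot_hour", quantity = 1),
                   uc, cpi_flat),
    "robot_hour")
})

test_that("perspective totals nest and respond only to their components", {
  uc <- unit_costs_2017(c("theatre_minute", "gp_visit"), c(10, 40))
  res <- tibble::tibble(id = 1L, phase = "index", item = "theatre_minute",
                        quantity = 100, day = 10)
  trial <- tiny_cost_trial(res)
  costs <- cost_patients(trial, uc, cpi_flat)
  # no follow-up and no out-of-pocket: all three perspectives equal
  expect_equal(costs$cost_intervention, costs$cost_nhs)
  expect_equal(costs$cost_nhs, costs$cost_societal)

  trial2 <- tiny_cost_trial(
    dplyr::bind_rows(res, tibble::tibble(id = 1L, phase = "followup",
                                         item = "gp_visit", quantity = 3,
                                         day = 400)),
    oop = tibble::tibble(id = 1L, description = "travel", amount = 25, day = 30))
  c2 <- cost_patients(trial2, uc, cpi_flat)
  expect_equal(c2$cost_intervention, 1000)
  expect_equal(c2$cost_nhs, 1120)
  expect_equal(c2$cost_societal, 1145)
  # adding an out-of-pocket item changes the societal perspective only
  expect_equal(c2$cost_nhs - costs$cost_nhs, 120)
  expect_error(total_cost(c2, "martian"), "perspective")
  expect_equal(total_cost(c2, "societal")$cost, 1145)
})

test_that("perspective nesting holds across a whole simulated trial", {
  trial <- simulate_trial(sim_config(n_per_arm = 40, seed = 2),
                          compute_truth = FALSE)
  costs <- cost_patients(trial)
  expect_true(all(costs$cost_intervention <= costs$cost_nhs + 1e-9))
  expect_true(all(costs$cost_nhs <= costs$cost_societal + 1e-9))
  expect_true(all(costs$cost_intervention >= 0))
})

test_that("no-noise group means equal the configured quantities exactly", {
  trial <- simulate_trial(no_noise_config(n_per_arm = 6), compute_truth = FALSE)
  costs <- cost_patients(trial) # default fixtures, undiscounted
  # hand-computed: 60 min of theatre+surgeon+anaesthetist+nurse (2016 prices),
  # 1 consumable pack, 1 bed-day (2015), 3 catheter days, 1 GP visit,
  # 1 outpatient visit (2016), GBP 25 out-of-pocket
  f16 <- 102.9 / 100.2
  f15 <- 102.9 / 98.0
  index <- 60 * (16 + 2.4 + 2.2 + 0.8) * f16 + 120 + 400 * f15 + 3 * 2.5
  followup <- 38 + 125 * f16
  expect_equal(unique(costs$cost_intervention), index, tolerance = 1e-12)
  expect_equal(unique(costs$cost_societal), index + followup + 25,
               tolerance = 1e-12)
})

test_that("second-year cost discounting divides year-2 components by 1.035", {
  uc <- unit_costs_2017("gp_visit", 100)
  res <- tibble::tibble(id = c(1L, 1L), phase = "followup", item = "gp_visit",
                        quantity = c(1, 1), day = c(100, 400))
  trial <- tiny_cost_trial(res)
  undisc <- cost_patients(trial, uc, cpi_flat, discount_rate = 0)
  disc <- cost_patients(trial, uc, cpi_flat, discount_rate = 0.035)
  expect_equal(undisc$cost_nhs, 200)
  expect_equal(disc$cost_nhs, 100 + 100 / 1.035)
})
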