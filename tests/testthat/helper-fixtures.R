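# Shared fixtures: configurations and hand-built objects used across files.

arms <- c("urethroplasty", "urethrotomy")

# A fully deterministic configuration: every distribution degenerate, no
# recurrence, crossover or missingness, identical utility trajectories on the
# tariff grid. `delta_oop` shifts the urethroplasty out-of-pocket mean, making
# the societal cost increment exactly `delta_oop`.
no_noise_config <- function(n_per_arm = 20, delta_oop = 0, seed = 42) {
  cfg <- sim_config(n_per_arm = n_per_arm, seed = seed)
  flat <- setNames(rep(0.85, length(eq5d_timepoints())), eq5d_timepoints())
  for (a in arms) {
    cfg$wait_days[[a]] <- c(mean = 40, sd = 0)
    cfg$cost_params[[a]] <- list(
      theatre_minutes = c(mean = 60, sd = 0),
      los_days = c(mean = 1, sd = 0),
      consumable_packs = c(mean = 1, sd = 0),
      catheter_days = 3,
      gp_visits = c(mean = 1, sd = 0),
      outpatient_visits = c(mean = 1, sd = 0),
      oop = c(mean = 25, sd = 0)
    )
    cfg$utility_params$trajectory[[a]] <- flat
  }
  cfg$cost_params$urethroplasty$oop <- c(mean = 25 + delta_oop, sd = 0)
  cfg$utility_params$between_sd <- 0
  cfg$utility_params$within_sd <- 0
  cfg$recurrence_hazard[] <- 0
  cfg$crossover_prob <- 0
  cfg$no_surgery_prob <- 0
  cfg$missing_rate$rates[] <- 0
  cfg$missing_rate$arm_coef <- 0
  cfg$missing_rate$baseline_coef <- 0
  cfg$n_truth <- 200
  cfg
}

# Noisy configuration with a built-in societal cost increment of `delta_oop`
# and identical utility trajectories (true QALY increment zero).
delta_config <- function(n_per_arm, delta_oop = 2000, seed = 42) {
  cfg <- sim_config(n_per_arm = n_per_arm, seed = seed)
  cfg$utility_params$trajectory$urethroplasty <-
    cfg$utility_params$trajectory$urethrotomy
  cfg$cost_params$urethroplasty <- cfg$cost_params$urethrotomy
  cfg$wait_days$urethroplasty <- cfg$wait_days$urethrotomy
  cfg$recurrence_hazard[] <- 0
  cfg$crossover_prob <- 0
  cfg$no_surgery_prob <- 0
  cfg$cost_params$urethroplasty$oop <-
    c(mean = cfg$cost_params$urethrotomy$oop[["mean"]] + delta_oop, sd = 60)
  cfg$missing_rate$rates[] <- 0
  cfg
}

# Minimal hand-built trial for costing tests (no observations needed).
tiny_cost_trial <- function(resources, oop = NULL) {
  ids <- unique(c(resources$id, oop$id, 1L))
  structure(
    list(
      patients = tibble::tibble(
        id = ids,
        arm_allocated = "urethroplasty", arm_received = "urethroplasty",
        stratum = "lt12m", had_index_surgery = TRUE, surgery_day = 10
      ),
      observations = tibble::tibble(),
      resources = resources,
      oop = oop %||% tibble::tibble(id = integer(0), description = character(0),
                                    amount = numeric(0), day = numeric(0)),
      reinterventions = tibble::tibble(),
      config = NULL, seed = 1, truth = NULL
    ),
    class = "uro_trial"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random analysis frames for regression-oracle tests.
random_frame <- function(n_per_arm = 40, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_arm
  tibble::tibble(
    id = seq_len(n),
    arm = rep(arms, each = n_per_arm),
    stratum = sample(c("lt12m", "ge12m"), n, replace = TRUE),
    baseline_utility = runif(n, 0.4, 1),
    cost = rgamma(n, 4, 1 / 800) + 1500 * (rep(c(1, 0), each = n_per_arm)),
    qaly = pmin(rnorm(n, 1.6, 0.3), 2),
    complete_case = TRUE
  )
}

unit_costs_2017 <- function(items, costs) {
  tibble::tibble(item = items, unit = "per unit", unit_cost = costs,
                 price_year = 2017)
}

cpi_flat <- tibble::tibble(year = 2015:2017, index = c(98.0, 100.2, 102.9))
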