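#' Synthetic trial configuration
#'
#' Describes the data-generating process for a two-arm (1:1) randomised trial
#' of open urethroplasty versus endoscopic urethrotomy with 24 months of
#' follow-up. Defaults mirror the scale and structure of a UK multicentre
#' trial in recurrent bulbar urethral stricture: 110 analysed participants per
#' arm, a binary minimisation stratum (time since last procedure < 12 vs >= 12
#' months), longer theatre time, length of stay and waiting time for
#' urethroplasty, a lower monthly re-intervention hazard after urethroplasty,
#' and EQ-5D-5L collected at the eleven scheduled points of
#' [eq5d_timepoints()] with missingness that increases over follow-up and
#' depends (missing at random) on arm and baseline utility.
#'
#' Quantity distributions are gamma, parameterised by mean and sd
#' (`sd = 0` gives the mean deterministically); counts are Poisson with the
#' same degenerate switch. Length-of-stay defaults (urethroplasty mean 1.34,
#' sd 0.95 days; urethrotomy 0.52, sd 1.0) are the published trial values.
#' Utility trajectory means sit on the 0.05 grid of [toy_tariff()] so that a
#' noise-free configuration reproduces them exactly after profile scoring.
#'
#' @param n_per_arm participants per allocated arm.
#' @param seed default random seed for [simulate_trial()].
#' @param stratum_prob probability of the "< 12 months since last procedure"
#'   stratum.
#' @param no_surgery_prob probability a participant never receives the index
#'   operation.
#' @param crossover_prob probability the received index procedure differs
#'   from allocation.
#' @param switch_prob probability a re-intervention uses the other procedure.
#' @param recurrence_hazard named per-procedure monthly probability of
#'   re-intervention over months 1-24 after surgery.
#' @param wait_days per-arm mean/sd of the randomisation-to-surgery delay.
#' @param cost_params per-arm resource-use distributions (see Details).
#' @param utility_params per-arm mean utility trajectory over
#'   [eq5d_timepoints()], between-patient sd (random intercept) and
#'   within-patient noise sd.
#' @param missing_rate list with per-timepoint `rates`, logistic MAR
#'   coefficients `arm_coef` (added for urethroplasty) and `baseline_coef`
#'   (per unit of centred baseline utility), and `preserve_baseline`.
#' @param n_truth simulated participants per arm used to compute the
#'   ground-truth record (large-sample expectation of the same process).
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_per_arm = 20, seed = 1)
#' trial <- simulate_trial(cfg, compute_truth = FALSE)
#' trial$patients
sim_config <- function(
    n_per_arm = 110,
    seed = 20170,
    stratum_prob = 0.5,
    no_surgery_prob = 0.03,
    crossover_prob = 0.05,
    switch_prob = 0.5,
    recurrence_hazard = c(urethroplasty = 0.004, urethrotomy = 0.012),
    wait_days = list(
      urethroplasty = c(mean = 90, sd = 25),
      urethrotomy = c(mean = 40, sd = 15)
    ),
    cost_params = list(
      urethroplasty = list(
        theatre_minutes = c(mean = 140, sd = 25),
        los_days = c(mean = 1.34, sd = 0.95),
        consumable_packs = c(mean = 2, sd = 1),
        catheter_days = 21,
        gp_visits = c(mean = 1.2, sd = 1),
        outpatient_visits = c(mean = 1.0, sd = 1),
        oop = c(mean = 30, sd = 45)
      ),
      urethrotomy = list(
        theatre_minutes = c(mean = 45, sd = 12),
        los_days = c(mean = 0.52, sd = 1.0),
        consumable_packs = c(mean = 1, sd = 1),
        catheter_days = 3,
        gp_visits = c(mean = 1.8, sd = 1),
        outpatient_visits = c(mean = 1.4, sd = 1),
        oop = c(mean = 25, sd = 40)
      )
    ),
    utility_params = list(
      trajectory = list(
        urethroplasty = c(
          baseline = 0.75, pre_surgery = 0.75, cath_1wk = 0.70,
          m3_post_surgery = 0.85, m6_post_surgery = 0.85,
          m9_post_surgery = 0.85, m12_post_surgery = 0.85,
          m24_post_surgery = 0.85, m18_post_rand = 0.85,
          m24_post_rand = 0.85, end_of_study = 0.85
        ),
        urethrotomy = c(
          baseline = 0.75, pre_surgery = 0.75, cath_1wk = 0.80,
          m3_post_surgery = 0.85, m6_post_surgery = 0.85,
          m9_post_surgery = 0.85, m12_post_surgery = 0.85,
          m24_post_surgery = 0.85, m18_post_rand = 0.85,
          m24_post_rand = 0.85, end_of_study = 0.85
        )
      ),
      between_sd = 0.15,
      within_sd = 0.05
    ),
    missing_rate = list(
      rates = c(
        baseline = 0, pre_surgery = 0.10, cath_1wk = 0.20,
        m3_post_surgery = 0.25, m6_post_surgery = 0.30,
        m9_post_surgery = 0.30, m12_post_surgery = 0.35,
        m24_post_surgery = 0.40, m18_post_rand = 0.35,
        m24_post_rand = 0.40, end_of_study = 0.45
      ),
      arm_coef = 0.4,
      baseline_coef = -4,
      preserve_baseline = TRUE
    ),
    n_truth = 10000) {
  cfg <- structure(
    list(
      n_per_arm = as.integer(n_per_arm), seed = seed,
      stratum_prob = stratum_prob, no_surgery_prob = no_surgery_prob,
      crossover_prob = crossover_prob, switch_prob = switch_prob,
      recurrence_hazard = recurrence_hazard, wait_days = wait_days,
      cost_params = cost_params, utility_params = utility_params,
      missing_rate = missing_rate, n_truth = as.integer(n_truth)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("Not a `sim_config` object.")
  if (cfg$n_per_arm < 1) abort("`n_per_arm` must be at least 1.")
  assert_probability(cfg$stratum_prob, "stratum_prob")
  assert_probability(cfg$no_surgery_prob, "no_surgery_prob")
  assert_probability(cfg$crossover_prob, "crossover_prob")
  assert_probability(cfg$switch_prob, "switch_prob")
  assert_probability(cfg$recurrence_hazard, "recurrence_hazard")
  if (!all(c("urethroplasty", "urethrotomy") %in% names(cfg$recurrence_hazard))) {
    abort("`recurrence_hazard` must be named for both procedures.")
  }
  for (arm in c("urethroplasty", "urethrotomy")) {
    assert_nonneg(cfg$wait_days[[arm]][["sd"]], paste0("wait_days$", arm, "[sd]"))
    cp <- cfg$cost_params[[arm]]
    for (nm in c("theatre_minutes", "los_days", "consumable_packs",
                 "gp_visits", "outpatient_visits", "oop")) {
      assert_nonneg(cp[[nm]][["mean"]], paste0("cost_params$", arm, "$", nm, "[mean]"))
      assert_nonneg(cp[[nm]][["sd"]], paste0("cost_params$", arm, "$", nm, "[sd]"))
    }
    traj <- cfg$utility_params$trajectory[[arm]]
    if (!identical(names(traj), eq5d_timepoints())) {
      abort(sprintf("utility_params$trajectory$%s must be named by eq5d_timepoints().", arm))
    }
    if (any(traj < -1 | traj > 1)) {
      abort(sprintf("utility_params$trajectory$%s means must lie in [-1, 1].", arm))
    }
  }
  assert_nonneg(cfg$utility_params$between_sd, "utility_params$between_sd")
  assert_nonneg(cfg$utility_params$within_sd, "utility_params$within_sd")
  rates <- cfg$missing_rate$rates
  if (!identical(names(rates), eq5d_timepoints())) {
    abort("missing_rate$rates must be named by eq5d_timepoints().")
  }
  assert_probability(rates, "missing_rate$rates")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_per_arm, "per arm, seed", x$seed, "\n")
  cat("  monthly recurrence hazard:",
      paste(names(x$recurrence_hazard), signif(x$recurrence_hazard, 3),
            collapse = ", "), "\n")
  invisible(x)
}
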