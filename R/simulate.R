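#' Simulate a synthetic two-arm stricture surgery trial
#'
#' Generates patient-level data with the structure the downstream analysis
#' assumes: allocation and received procedure (with possible crossover), the
#' minimisation stratum, randomisation-to-surgery waiting time, itemised
#' index-procedure resource use, re-intervention events from a geometric
#' monthly hazard over months 1-24 after surgery (with possible treatment
#' switching), follow-up primary/secondary care contacts, out-of-pocket
#' spending, and EQ-5D-5L profiles at the scheduled collection points with
#' configurable (MAR) missingness. All observation days are capped at 760 days
#' from randomisation.
#'
#' Latent utilities are converted to EQ-5D-5L profiles on the 0.05 decrement
#' grid of [toy_tariff()] using randomised rounding, so the expected scored
#' utility equals the latent value and a noise-free configuration reproduces
#' the trajectory means exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. Identical seeds
#'   reproduce identical datasets.
#' @param compute_truth also simulate a large-sample ground-truth record
#'   (see [compute_truth()]); skip when generating many replicates from one
#'   configuration.
#' @return an object of class `uro_trial`: a list of tibbles `patients`,
#'   `observations`, `resources`, `oop`, `reinterventions`, plus the `config`
#'   and, if requested, a `truth` record.
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(n_per_arm = 15, seed = 7),
#'                         compute_truth = FALSE)
#' dplyr::count(trial$patients, arm_allocated)
simulate_trial <- function(config = sim_config(), seed = config$seed,
                           compute_truth = TRUE) {
  validate_sim_config(config)
  core <- simulate_core(config, config$n_per_arm, stage_seed(seed, "simulate"))
  trial <- structure(
    c(core, list(config = config, seed = seed, truth = NULL)),
    class = "uro_trial"
  )
  mr <- config$missing_rate
  trial <- apply_missingness(
    trial,
    rates = mr$rates, arm_coef = mr$arm_coef,
    baseline_coef = mr$baseline_coef,
    preserve_baseline = isTRUE(mr$preserve_baseline),
    seed = stage_seed(seed, "missing")
  )
  if (compute_truth) {
    trial$truth <- compute_truth(config, seed = seed)
  }
  trial
}

#' @export
print.uro_trial <- function(x, ...) {
  cat("<uro_trial>", nrow(x$patients), "patients,",
      nrow(x$observations), "scheduled EQ-5D-5L observations,",
      nrow(x$reinterventions), "re-interventions\n")
  invisible(x)
}

# Complete-data generation shared by simulate_trial() and compute_truth().
simulate_core <- function(config, n_per_arm, seed) {
  set.seed(seed)
  n <- 2L * n_per_arm
  arms <- c("urethroplasty", "urethrotomy")
  arm_allocated <- rep(arms, each = n_per_arm)
  stratum <- ifelse(runif(n) < config$stratum_prob, "lt12m", "ge12m")
  crossed <- runif(n) < config$crossover_prob
  arm_received <- ifelse(crossed, other_arm(arm_allocated), arm_allocated)
  had_surgery <- runif(n) >= config$no_surgery_prob

  wait <- numeric(n)
  for (a in arms) {
    i <- arm_received == a
    w <- config$wait_days[[a]]
    wait[i] <- pmax(2, pmin(365, round(rgamma_ms(sum(i), w[["mean"]], w[["sd"]]))))
  }
  surgery_day <- ifelse(had_surgery, wait, NA_real_)

  patients <- tibble(
    id = seq_len(n),
    arm_allocated = arm_allocated,
    arm_received = arm_received,
    stratum = stratum,
    had_index_surgery = had_surgery,
    surgery_day = surgery_day
  )

  # --- index procedure resource use -------------------------------------
  res_index <- procedure_resource_rows(
    id = patients$id[had_surgery],
    proc = arm_received[had_surgery],
    day = surgery_day[had_surgery],
    config = config, phase = "index"
  )

  # --- re-interventions: geometric monthly hazard, months 1..24 ---------
  sidx <- which(had_surgery)
  last_proc <- arm_received[sidx]
  ev_id <- integer(0); ev_day <- numeric(0); ev_proc <- character(0)
  for (m in 1:24) {
    h <- config$recurrence_hazard[last_proc]
    event <- runif(length(sidx)) < h
    day <- surgery_day[sidx] + round(m * 30.4375)
    switch_draw <- runif(length(sidx)) < config$switch_prob
    keep <- event & day <= 760
    if (any(keep)) {
      new_proc <- ifelse(switch_draw[keep], other_arm(last_proc[keep]),
                         last_proc[keep])
      ev_id <- c(ev_id, patients$id[sidx][keep])
      ev_day <- c(ev_day, day[keep])
      ev_proc <- c(ev_proc, new_proc)
      last_proc[keep] <- new_proc
    }
  }
  reinterventions <- tibble(id = ev_id, day = ev_day, procedure = ev_proc)
  res_reint <- procedure_resource_rows(
    id = ev_id, proc = ev_proc, day = ev_day,
    config = config, phase = "reintervention"
  )

  # --- follow-up contacts (24-month recall) ------------------------------
  res_follow <- list_rbind(map(
    c(gp_visits = "gp_visit", outpatient_visits = "outpatient_visit"),
    function(item) {
      out <- vector("list", 2)
      for (k in seq_along(arms)) {
        a <- arms[k]
        par <- config$cost_params[[a]][[
          if (item == "gp_visit") "gp_visits" else "outpatient_visits"]]
        i <- which(arm_received == a)
        if (par[["sd"]] == 0) {
          out[[k]] <- tibble(id = patients$id[i], phase = "followup",
                             item = item, quantity = par[["mean"]], day = 365)
        } else {
          counts <- rcount_ms(length(i), par[["mean"]], par[["sd"]])
          ids <- rep(patients$id[i], counts)
          out[[k]] <- tibble(id = ids, phase = "followup", item = item,
                             quantity = 1,
                             day = round(runif(length(ids), 0, 730)))
        }
      }
      list_rbind(out)
    }
  ))
  resources <- bind_rows(res_index, res_reint, res_follow) |>
    arrange(.data$id, .data$day, .data$item)

  # --- out-of-pocket spending -------------------------------------------
  oop <- list_rbind(map(arms, function(a) {
    par <- config$cost_params[[a]]$oop
    i <- which(arm_received == a)
    amt <- rgamma_ms(length(i), par[["mean"]], par[["sd"]])
    day <- if (par[["sd"]] == 0) rep(365, length(i)) else round(runif(length(i), 0, 730))
    tibble(id = patients$id[i], description = "out_of_pocket",
           amount = amt, day = day)
  })) |> arrange(.data$id)

  # --- EQ-5D-5L observations --------------------------------------------
  observations <- simulate_observations(patients, config)

  list(patients = patients, observations = observations,
       resources = resources, oop = oop, reinterventions = reinterventions)
}

# Itemised resource rows for one operation per (id, proc, day) triple:
# theatre/staff minutes, consumable packs, bed-days and catheter days.
procedure_resource_rows <- function(id, proc, day, config, phase) {
  if (length(id) == 0) {
    return(tibble(id = integer(0), phase = character(0), item = character(0),
                  quantity = numeric(0), day = numeric(0)))
  }
  n <- length(id)
  theatre <- numeric(n); los <- numeric(n); packs <- numeric(n); cath <- numeric(n)
  for (a in c("urethroplasty", "urethrotomy")) {
    i <- proc == a
    if (!any(i)) next
    cp <- config$cost_params[[a]]
    theatre[i] <- rgamma_ms(sum(i), cp$theatre_minutes[["mean"]],
                            cp$theatre_minutes[["sd"]])
    los[i] <- rgamma_ms(sum(i), cp$los_days[["mean"]], cp$los_days[["sd"]])
    packs[i] <- rcount_ms(sum(i), cp$consumable_packs[["mean"]],
                          cp$consumable_packs[["sd"]])
    cath[i] <- cp$catheter_days
  }
  tibble(
    id = rep(id, times = 6),
    phase = phase,
    item = rep(c("theatre_minute", "surgeon_minute", "anaesthetist_minute",
                 "nurse_minute", "consumable_pack", "bed_day"), each = n),
    quantity = c(theatre, theatre, theatre, theatre, packs, los),
    day = rep(day, times = 6)
  ) |>
    bind_rows(tibble(id = id, phase = phase, item = "catheter_day",
                     quantity = cath, day = day))
}

# Scheduled EQ-5D-5L observations with latent utilities mapped to profiles.
simulate_observations <- function(patients, config) {
  up <- config$utility_params
  n <- nrow(patients)
  b <- rnorm(n, 0, up$between_sd)

  sched <- tidyr::crossing(id = patients$id, timepoint = eq5d_timepoints()) |>
    left_join(patients, by = "id") |>
    filter(.data$had_index_surgery |
             .data$timepoint %in% rand_anchored_timepoints())

  cath_days <- map_dbl(sched$arm_received,
                       ~ config$cost_params[[.x]]$catheter_days)
  sd_ <- sched$surgery_day
  day <- dplyr::case_match(
    sched$timepoint,
    "baseline" ~ 0,
    "pre_surgery" ~ sd_ - 1,
    "cath_1wk" ~ sd_ + cath_days + 7,
    "m3_post_surgery" ~ sd_ + 91,
    "m6_post_surgery" ~ sd_ + 183,
    "m9_post_surgery" ~ sd_ + 274,
    "m12_post_surgery" ~ sd_ + 365,
    "m24_post_surgery" ~ sd_ + 730,
    "m18_post_rand" ~ 548,
    "m24_post_rand" ~ 730,
    "end_of_study" ~ 745
  )
  sched$day <- pmin(day, 760)

  traj <- do.call(rbind, up$trajectory[c("urethroplasty", "urethrotomy")])
  mu <- traj[cbind(match(sched$arm_received, c("urethroplasty", "urethrotomy")),
                   match(sched$timepoint, eq5d_timepoints()))]
  u <- mu + b[match(sched$id, patients$id)] +
    rnorm(nrow(sched), 0, up$within_sd)
  u <- pmin(pmax(u, 0), 1)

  lv <- utility_to_levels(u)
  out <- tibble(
    id = sched$id, timepoint = sched$timepoint, day = sched$day
  )
  out[eq5d_dimensions()] <- as.data.frame(lv)
  out |>
    arrange(.data$id, .data$day,
            match(.data$timepoint, eq5d_timepoints()))
}

# Map latent utilities to EQ-5D-5L levels on the toy 0.05 decrement grid with
# randomised rounding (unbiased in expectation). The total decrement is spread
# over the five dimensions by a random rotation.
utility_to_levels <- function(u, step = 0.05) {
  d_real <- (1 - u) / step
  d <- floor(d_real)
  frac <- d_real - d
  d <- d + (runif(length(u)) < frac)
  d <- pmin(pmax(d, 0), 20)
  base <- d %/% 5
  rem <- d %% 5
  start <- floor(runif(length(u)) * 5)
  pos <- outer(rep(1, length(u)), 0:4)
  extra <- ((pos - start) %% 5) < rem
  lv <- base + extra + 1
  colnames(lv) <- eq5d_dimensions()
  lv
}

#' Apply (MAR) missingness to scheduled EQ-5D-5L observations
#'
#' Each scheduled observation is independently set missing with its
#' per-timepoint probability, optionally shifted on the logit scale by arm and
#' by centred baseline utility (a missing-at-random mechanism: the shift uses
#' only observed baseline data). Rates of exactly 0 or 1 are honoured exactly.
#'
#' @param trial a `uro_trial` with complete observations, or one already
#'   containing missing values (missingness is only ever added).
#' @param rates a single probability applied to every timepoint, or a vector
#'   named by [eq5d_timepoints()].
#' @param arm_coef logit shift added for the urethroplasty arm.
#' @param baseline_coef logit shift per unit of centred baseline utility.
#' @param preserve_baseline never remove the baseline observation.
#' @param tariff tariff used to score baseline utility for the MAR shift.
#' @param seed optional seed.
#' @return the trial with dimension levels set to `NA` where missing.
#' @export
apply_missingness <- function(trial, rates, arm_coef = 0, baseline_coef = 0,
                              preserve_baseline = TRUE,
                              tariff = toy_tariff(), seed = NULL) {
  stopifnot(inherits(trial, "uro_trial"))
  obs <- trial$observations
  if (length(rates) == 1 && is.null(names(rates))) {
    rates <- setNames(rep(rates, length(eq5d_timepoints())), eq5d_timepoints())
  }
  assert_probability(rates, "rates")
  if (!all(obs$timepoint %in% names(rates))) {
    abort("`rates` must cover every scheduled timepoint present.")
  }
  if (!is.null(seed)) set.seed(seed)

  base_u <- obs |>
    add_utilities(tariff) |>
    filter(.data$timepoint == "baseline") |>
    select("id", base_utility = "utility")
  centre <- mean(base_u$base_utility, na.rm = TRUE)
  if (!is.finite(centre)) centre <- 0

  df <- obs |>
    left_join(trial$patients[, c("id", "arm_allocated")], by = "id") |>
    left_join(base_u, by = "id")
  r <- unname(rates[df$timepoint])
  shift <- arm_coef * (df$arm_allocated == "urethroplasty") +
    baseline_coef * (dplyr::coalesce(df$base_utility, centre) - centre)
  p <- ifelse(r <= 0, 0, ifelse(r >= 1, 1, plogis(qlogis(r) + shift)))
  drop <- runif(nrow(df)) < p
  if (preserve_baseline) drop[df$timepoint == "baseline"] <- FALSE
  for (dim in eq5d_dimensions()) {
    obs[[dim]][drop] <- NA_integer_
  }
  trial$observations <- obs
  trial
}

#' Ground-truth record for a configuration
#'
#' The large-sample expectation of the generating process: per-arm
#' (intention-to-treat) mean costs by perspective, mean 24-month QALY
#' (randomisation-anchored, unrescaled, undiscounted), their incrementals
#' (urethroplasty minus urethrotomy), and the analytic 24-month recurrence
#' probability `1 - (1 - hazard)^24`. Computed by re-simulating `n_truth`
#' participants per arm from the same configuration without missingness; for
#' a noise-free configuration the record is exact.
#'
#' @param config a [sim_config()].
#' @param seed root seed (a truth-specific stream is derived from it).
#' @param n_truth participants per arm (defaults to `config$n_truth`).
#' @param unit_costs,cpi,tariff pricing and scoring inputs.
#' @return an object of class `uro_truth`: tibble with one row per arm plus
#'   attributes `delta_cost` (societal) and `delta_qaly`.
#' @export
compute_truth <- function(config, seed = config$seed,
                          n_truth = config$n_truth,
                          unit_costs = default_unit_costs(),
                          cpi = default_cpi(),
                          tariff = toy_tariff()) {
  core <- simulate_core(config, n_truth, stage_seed(seed, "truth"))
  big <- structure(c(core, list(config = config, seed = seed)),
                   class = "uro_trial")
  costs <- cost_patients(big, unit_costs, cpi)
  qalys <- compute_qalys(big, tariff = tariff,
                         analysis = "post_randomisation")
  df <- big$patients |>
    left_join(costs, by = "id") |>
    left_join(qalys[, c("id", "qaly")], by = "id") |>
    group_by(arm = .data$arm_allocated) |>
    summarise(
      mean_cost_intervention = mean(.data$cost_intervention),
      mean_cost_nhs = mean(.data$cost_nhs),
      mean_cost_societal = mean(.data$cost_societal),
      mean_qaly = mean(.data$qaly, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(recurrence_prob_24m =
             1 - (1 - config$recurrence_hazard[.data$arm])^24)
  truth <- df[match(c("urethroplasty", "urethrotomy"), df$arm), ]
  structure(truth,
            class = c("uro_truth", class(truth)),
            # increments are urethroplasty minus urethrotomy throughout
            delta_cost = truth$mean_cost_societal[1] - truth$mean_cost_societal[2],
            delta_qaly = truth$mean_qaly[1] - truth$mean_qaly[2],
            n_truth = n_truth)
}

#' Write / read a trial as delimited text
#'
#' `patients.csv` holds one row per participant; `observations.csv` is the
#' long EQ-5D-5L table (blank levels where missing); resource use,
#' out-of-pocket items and re-interventions get their own tables; the
#' configuration seed is recorded in `config.yaml`.
#'
#' @param trial a `uro_trial`.
#' @param dir output directory (created if needed).
#' @return `write_trial_data()` returns the directory invisibly;
#'   `read_trial_data()` returns a `uro_trial` (without truth/config unless
#'   present on disk).
#' @export
write_trial_data <- function(trial, dir) {
  stopifnot(inherits(trial, "uro_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(trial$patients, file.path(dir, "patients.csv"))
  readr::write_csv(trial$observations, file.path(dir, "observations.csv"))
  readr::write_csv(trial$resources, file.path(dir, "resources.csv"))
  readr::write_csv(trial$oop, file.path(dir, "oop.csv"))
  readr::write_csv(trial$reinterventions, file.path(dir, "reinterventions.csv"))
  yaml::write_yaml(list(seed = trial$seed, n_per_arm = trial$config$n_per_arm),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f),
                                    show_col_types = FALSE, progress = FALSE)
  structure(
    list(
      patients = rd("patients.csv"), observations = rd("observations.csv"),
      resources = rd("resources.csv"), oop = rd("oop.csv"),
      reinterventions = rd("reinterventions.csv"),
      config = NULL, seed = NULL, truth = NULL
    ),
    class = "uro_trial"
  )
}
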