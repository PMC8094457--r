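#' Specify the three-state cohort Markov model
#'
#' The decision model follows a cohort over a 10-year horizon through three
#' health states: symptom-free (after a successful procedure), symptomatic
#' (stricture recurrence awaiting re-intervention) and deceased (absorbing).
#' Each strategy starts the whole cohort symptom-free immediately after its
#' initial procedure, whose cost is incurred at time zero. Per cycle, death
#' (a flat background rate) is applied first and recurrence among survivors
#' second, so rows of every transition matrix sum to one without
#' renormalisation. The recurrence probability depends on the *last procedure
#' received*; symptomatic survivors are re-intervened within the cycle and
#' return to symptom-free, with the re-intervention procedure chosen by the
#' recurrence policy: `"observed_mix"` switches procedure with probability
#' `p_switch`, `"always_same"` repeats the last procedure, `"always_other"`
#' always uses the other one. Costs and QALYs accrue at cycle-start times and
#' are discounted at 3.5% a year by default; an optional half-cycle correction
#' averages start- and end-of-cycle occupancy.
#'
#' @param procedures named list (`urethroplasty`, `urethrotomy`), each with
#'   `procedure_cost` (initial and re-intervention cost, GBP) and `p_recur`
#'   (per-cycle recurrence probability after that procedure).
#' @param p_death per-cycle background death probability (age-independent).
#' @param u_symptom_free,u_symptomatic state utilities (<= 1).
#' @param followup_cost per-cycle cost while alive (GBP).
#' @param recurrence_policy `"observed_mix"`, `"always_same"` or
#'   `"always_other"`.
#' @param p_switch probability a re-intervention switches procedure under
#'   `"observed_mix"`.
#' @param recurrence_utility_decrement one-off QALY loss per recurrence event
#'   (default 0: transient recovery losses are not modelled in the base
#'   structure).
#' @param cycle_length cycle length in years (default 0.5, matching 6-monthly
#'   follow-up).
#' @param horizon model horizon in years (default 10); must be a whole number
#'   of cycles.
#' @param discount_rate_costs,discount_rate_qalys annual discount rates.
#' @param half_cycle apply a half-cycle correction.
#' @return object of class `markov_spec`.
#' @export
markov_spec <- function(
    procedures = list(
      urethroplasty = list(procedure_cost = 4332, p_recur = 0.048),
      urethrotomy = list(procedure_cost = 2209, p_recur = 0.067)
    ),
    p_death = 0.004,
    u_symptom_free = 0.930,
    u_symptomatic = 0.808,
    followup_cost = 78,
    recurrence_policy = c("observed_mix", "always_same", "always_other"),
    p_switch = 0.55,
    recurrence_utility_decrement = 0,
    cycle_length = 0.5,
    horizon = 10,
    discount_rate_costs = 0.035,
    discount_rate_qalys = 0.035,
    half_cycle = FALSE) {
  spec <- structure(
    list(
      procedures = procedures, p_death = p_death,
      u_symptom_free = u_symptom_free, u_symptomatic = u_symptomatic,
      followup_cost = followup_cost,
      recurrence_policy = match.arg(recurrence_policy),
      p_switch = p_switch,
      recurrence_utility_decrement = recurrence_utility_decrement,
      cycle_length = cycle_length, horizon = horizon,
      discount_rate_costs = discount_rate_costs,
      discount_rate_qalys = discount_rate_qalys,
      half_cycle = isTRUE(half_cycle)
    ),
    class = "markov_spec"
  )
  validate_markov_spec(spec)
  spec
}

validate_markov_spec <- function(spec) {
  for (p in c("urethroplasty", "urethrotomy")) {
    pr <- spec$procedures[[p]]
    if (is.null(pr)) abort(sprintf("procedures$%s is missing.", p))
    assert_nonneg(pr$procedure_cost, paste0("procedures$", p, "$procedure_cost"))
    assert_probability(pr$p_recur, paste0("procedures$", p, "$p_recur"))
  }
  assert_probability(spec$p_death, "p_death")
  assert_probability(spec$p_switch, "p_switch")
  if (spec$u_symptom_free > 1 || spec$u_symptomatic > 1) {
    abort("State utilities must not exceed 1.")
  }
  assert_nonneg(spec$followup_cost, "followup_cost")
  assert_nonneg(spec$recurrence_utility_decrement,
                "recurrence_utility_decrement")
  if (spec$cycle_length <= 0) abort("`cycle_length` must be positive.")
  n_cycles <- spec$horizon / spec$cycle_length
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    abort("`horizon` must be a whole number of cycles.")
  }
  invisible(spec)
}

#' Read a Markov specification from YAML
#'
#' @param path YAML file whose keys match the arguments of [markov_spec()].
#' @return a `markov_spec`.
#' @export
read_markov_spec <- function(path) {
  do.call(markov_spec, yaml::read_yaml(path))
}

#' @rdname read_markov_spec
#' @export
default_markov_spec <- function() {
  read_markov_spec(system.file("extdata", "markov_params.yaml",
                               package = "urocea"))
}

# Re-intervention procedure mix given the last procedure received.
reintervention_mix <- function(spec, last_procedure) {
  other <- other_arm(last_procedure)
  switch(spec$recurrence_policy,
    always_same = setNames(c(1, 0), c(last_procedure, other)),
    always_other = setNames(c(0, 1), c(last_procedure, other)),
    observed_mix = setNames(c(1 - spec$p_switch, spec$p_switch),
                            c(last_procedure, other))
  )
}

#' Single-cycle transition matrix
#'
#' The 3 x 3 row-stochastic matrix over (symptom-free, symptomatic, deceased)
#' given the last procedure received, applying death first and recurrence
#' among survivors (multiplicative competing risks). Symptomatic survivors are
#' re-intervened within the cycle and return to symptom-free; the procedure
#' mix implied by the recurrence policy is attached as the
#' `"reintervention_mix"` attribute.
#'
#' @param spec a [markov_spec()].
#' @param last_procedure `"urethroplasty"` or `"urethrotomy"`.
#' @return 3 x 3 matrix with rows summing to 1 (deceased absorbing).
#' @export
build_transition_matrix <- function(spec, last_procedure) {
  validate_markov_spec(spec)
  last_procedure <- match.arg(last_procedure,
                              c("urethroplasty", "urethrotomy"))
  d <- spec$p_death
  r <- spec$procedures[[last_procedure]]$p_recur
  m <- matrix(c(
    (1 - d) * (1 - r), (1 - d) * r, d,
    (1 - d), 0, d,
    0, 0, 1
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("symptom_free", "symptomatic", "deceased"),
                  c("symptom_free", "symptomatic", "deceased")))
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12))
  attr(m, "reintervention_mix") <- reintervention_mix(spec, last_procedure)
  m
}

#' Run the cohort model for one strategy
#'
#' Propagates state occupancy (internally expanded by last procedure
#' received) over the horizon, accruing discounted costs and QALYs.
#'
#' @param spec a [markov_spec()].
#' @param strategy initial procedure, `"urethroplasty"` or `"urethrotomy"`.
#' @param trace keep the per-cycle trace (disable inside tight PSA loops).
#' @return object of class `cohort_run`: `cost` and `qaly` (discounted
#'   totals), `cost_undiscounted`, `qaly_undiscounted`, and the per-cycle
#'   `trace` tibble (state occupancy sums to 1 every cycle).
#' @export
run_cohort <- function(spec, strategy = c("urethroplasty", "urethrotomy"),
                       trace = TRUE) {
  validate_markov_spec(spec)
  strategy <- match.arg(strategy)
  procs <- c("urethroplasty", "urethrotomy")
  cl <- spec$cycle_length
  n_cycles <- round(spec$horizon / cl)
  d <- spec$p_death
  r <- vapply(procs, function(p) spec$procedures[[p]]$p_recur, numeric(1))
  cost_proc <- vapply(procs, function(p) spec$procedures[[p]]$procedure_cost,
                      numeric(1))
  mix <- lapply(setNames(procs, procs),
                function(p) reintervention_mix(spec, p)[procs])

  # occupancy: sf and sym, each split by last procedure, plus deceased
  occ <- c(sf = setNames(c(0, 0), procs), sym = setNames(c(0, 0), procs),
           dead = 0)
  occ[paste0("sf.", strategy)] <- 1

  step <- function(occ) {
    sf <- occ[paste0("sf.", procs)]
    sym <- occ[paste0("sym.", procs)]
    sf_stay <- sf * (1 - d) * (1 - r)
    sym_new <- sf * (1 - d) * r
    # symptomatic survivors are re-intervened and return symptom-free,
    # relabelled by the procedure mix of the policy
    reint_by_proc <- colSums(rbind(
      sym[1] * (1 - d) * mix[[procs[1]]],
      sym[2] * (1 - d) * mix[[procs[2]]]
    ))
    out <- occ
    out[paste0("sf.", procs)] <- sf_stay + reint_by_proc
    out[paste0("sym.", procs)] <- sym_new
    out["dead"] <- occ["dead"] + sum(sf) * d + sum(sym) * d
    out
  }

  keep_trace <- isTRUE(trace)
  trace_rows <- if (keep_trace) vector("list", n_cycles) else NULL
  cost_disc <- qaly_disc <- cost_undisc <- qaly_undisc <- 0
  for (t in seq_len(n_cycles) - 1) {
    time <- t * cl
    dfc <- (1 + spec$discount_rate_costs)^(-time)
    dfq <- (1 + spec$discount_rate_qalys)^(-time)
    occ_end <- step(occ)

    sf <- sum(occ[paste0("sf.", procs)])
    sym_by <- occ[paste0("sym.", procs)]
    sym <- sum(sym_by)
    alive <- sf + sym
    if (spec$half_cycle) {
      sf_e <- sum(occ_end[paste0("sf.", procs)])
      sym_e <- sum(occ_end[paste0("sym.", procs)])
      sf_r <- (sf + sf_e) / 2; sym_r <- (sym + sym_e) / 2
      alive_r <- sf_r + sym_r
      dfc <- (1 + spec$discount_rate_costs)^(-(time + cl / 2))
      dfq <- (1 + spec$discount_rate_qalys)^(-(time + cl / 2))
    } else {
      sf_r <- sf; sym_r <- sym; alive_r <- alive
    }

    reint_cost <- sum(vapply(procs, function(p) {
      unname(sym_by[paste0("sym.", p)]) * (1 - d) *
        sum(mix[[p]] * cost_proc)
    }, numeric(1)))
    new_recur <- sum(occ[paste0("sf.", procs)] * (1 - d) * r)

    cycle_cost <- spec$followup_cost * alive_r + reint_cost +
      if (t == 0) unname(cost_proc[strategy]) else 0
    cycle_qaly <- (spec$u_symptom_free * sf_r +
                     spec$u_symptomatic * sym_r) * cl -
      spec$recurrence_utility_decrement * new_recur

    cost_disc <- cost_disc + cycle_cost * dfc
    qaly_disc <- qaly_disc + cycle_qaly * dfq
    cost_undisc <- cost_undisc + cycle_cost
    qaly_undisc <- qaly_undisc + cycle_qaly

    stopifnot(abs(sf + sym + unname(occ["dead"]) - 1) < 1e-12)
    if (keep_trace) {
      trace_rows[[t + 1]] <- tibble(
        cycle = t, time = time,
        symptom_free = sf, symptomatic = sym, deceased = unname(occ["dead"]),
        cycle_cost = cycle_cost, cycle_qaly = cycle_qaly,
        cum_cost_discounted = cost_disc, cum_qaly_discounted = qaly_disc
      )
    }
    occ <- occ_end
  }
  structure(
    list(strategy = strategy, cost = cost_disc, qaly = qaly_disc,
         cost_undiscounted = cost_undisc, qaly_undiscounted = qaly_undisc,
         trace = if (keep_trace) list_rbind(trace_rows) else NULL,
         spec = spec),
    class = "cohort_run"
  )
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("<cohort_run> %s: discounted cost %.0f, QALY %.3f over %g years\n",
              x$strategy, x$cost, x$qaly, x$spec$horizon))
  invisible(x)
}

#' Run and compare both strategies
#'
#' @param spec a [markov_spec()].
#' @return object of class `markov_result`: per-strategy tibble `results`,
#'   increments (urethroplasty minus urethrotomy), `icer` classification and
#'   the two `cohort_run`s.
#' @export
run_strategies <- function(spec) {
  runs <- lapply(setNames(c("urethroplasty", "urethrotomy"),
                          c("urethroplasty", "urethrotomy")),
                 function(s) run_cohort(spec, s))
  results <- tibble(
    strategy = names(runs),
    cost = unname(map_dbl(runs, "cost")),
    qaly = unname(map_dbl(runs, "qaly"))
  )
  dc <- results$cost[1] - results$cost[2]
  de <- results$qaly[1] - results$qaly[2]
  structure(
    list(results = results, delta_cost = dc, delta_qaly = de,
         icer = classify_icer(dc, de), runs = runs, spec = spec),
    class = "markov_result"
  )
}

#' @export
print.markov_result <- function(x, ...) {
  print(x$results)
  cat(sprintf("  incremental cost %.0f, incremental QALY %.4f; %s\n",
              x$delta_cost, x$delta_qaly,
              if (x$icer$label == "icer") sprintf("ICER %.0f", x$icer$icer)
              else x$icer$label))
  invisible(x)
}

#' Deterministic scenario analyses
#'
#' Reproduces the four reported analyses: the base case (parameters from
#' participants who were allocated and received their allocated treatment,
#' observed re-intervention mix), parameters based on treatment received, and
#' the two recurrence-policy scenarios (always the same / always the other
#' treatment at recurrence). Optionally attaches CEAC probabilities from a
#' probabilistic sensitivity analysis per scenario.
#'
#' @param spec base-case [markov_spec()].
#' @param received_spec optional spec parameterised on treatment received;
#'   omitted when `NULL`.
#' @param psa_spec optional [psa_spec()] table; when supplied, a PSA with
#'   `n_draws` draws is run per scenario and CEAC probabilities at `lambda`
#'   are appended.
#' @param n_draws,lambda,seed PSA settings.
#' @return tibble with one row per analysis and strategy: discounted `cost`
#'   and `qaly`, `icer` (NA off the icer label), `label`, and probability
#'   columns when a PSA is attached.
#' @export
run_scenarios <- function(spec, received_spec = NULL, psa_spec = NULL,
                          n_draws = 1000,
                          lambda = c(0, 10000, 20000, 30000, 50000),
                          seed = NULL) {
  scen <- list(base_case = spec)
  if (!is.null(received_spec)) scen$treatment_received <- received_spec
  same <- spec; same$recurrence_policy <- "always_same"
  other <- spec; other$recurrence_policy <- "always_other"
  scen$always_same <- same
  scen$always_other <- other

  rows <- imap(scen, function(s, name) {
    res <- run_strategies(s)
    out <- res$results |>
      mutate(analysis = name, .before = 1) |>
      mutate(label = c(res$icer$label, ""), icer = res$icer$icer)
    if (!is.null(psa_spec)) {
      ps_tab <- if (is.function(psa_spec)) psa_spec(s) else psa_spec
      ps <- psa(s, ps_tab, n_draws = n_draws,
                seed = (seed %||% 1) + nchar(name))
      cc <- ps$ceac |>
        filter(.data$lambda %in% lambda) |>
        tidyr::pivot_wider(names_from = "lambda", values_from = "probability",
                           names_prefix = "p_wtp_")
      out <- out |> left_join(cc, by = "strategy")
    }
    out
  })
  list_rbind(rows)
}
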