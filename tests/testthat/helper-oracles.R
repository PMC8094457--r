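# Independent test oracles, deliberately written against the model
# *description* rather than the engine code.

# Individual-level micro-simulation of the three-state process: death first,
# recurrence among symptom-free survivors, symptomatic survivors re-intervened
# within the cycle (procedure by policy), rewards accrued at cycle starts.
markov_microsim <- function(spec, strategy, n = 1e5, seed = 1) {
  set.seed(seed)
  procs <- c("urethroplasty", "urethrotomy")
  r_by <- vapply(procs, function(p) spec$procedures[[p]]$p_recur, numeric(1))
  c_by <- vapply(procs, function(p) spec$procedures[[p]]$procedure_cost,
                 numeric(1))
  cl <- spec$cycle_length
  n_cycles <- round(spec$horizon / cl)
  state <- rep(1L, n) # 1 symptom-free, 2 symptomatic, 3 deceased
  last <- rep(strategy, n)
  cost <- rep(c_by[strategy], n)
  qaly <- numeric(n)
  for (t in 0:(n_cycles - 1)) {
    dfc <- (1 + spec$discount_rate_costs)^(-t * cl)
    dfq <- (1 + spec$discount_rate_qalys)^(-t * cl)
    alive <- state != 3L
    u <- ifelse(state == 1L, spec$u_symptom_free,
                ifelse(state == 2L, spec$u_symptomatic, 0))
    qaly <- qaly + u * cl * dfq
    cost <- cost + as.numeric(alive) * spec$followup_cost * dfc

    die <- alive & (runif(n) < spec$p_death)
    surv_sf <- state == 1L & alive & !die
    surv_sym <- state == 2L & alive & !die
    rec <- surv_sf & (runif(n) < r_by[last])
    sw <- switch(spec$recurrence_policy,
      always_same = rep(FALSE, n),
      always_other = rep(TRUE, n),
      observed_mix = runif(n) < spec$p_switch
    )
    newp <- ifelse(sw, ifelse(last == procs[1], procs[2], procs[1]), last)
    cost <- cost + as.numeric(surv_sym) * c_by[newp] * dfc
    last[surv_sym] <- newp[surv_sym]
    state[die] <- 3L
    state[surv_sym] <- 1L
    state[rec] <- 2L
  }
  list(cost = mean(cost), qaly = mean(qaly),
       se_cost = sd(cost) / sqrt(n), se_qaly = sd(qaly) / sqrt(n))
}

# Hand trapezoid, used to cross-check the AUC implementation.
trapz_by_hand <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}
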