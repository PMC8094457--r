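#' Within-trial cost-utility analysis
#'
#' Runs the complete-case intention-to-treat analysis for one analysis
#' variant: per-patient costs (second-year components discounted at 3.5% a
#' year by default) and QALYs are assembled, participants satisfying the
#' complete-case rules (complete cost *and* QALY data) are retained, the cost
#' and QALY equations are fit jointly by seemingly unrelated regression
#' adjusting for the minimisation stratum, allocated arm and baseline utility,
#' the incremental pair is classified (ICER or dominance), and a stratified
#' bootstrap supplies percentile confidence intervals and the
#' cost-effectiveness acceptability curve.
#'
#' @param trial a `uro_trial`.
#' @param unit_costs,cpi,target_year pricing inputs.
#' @param tariff an [eq5d_tariff()].
#' @param analysis QALY window: `"post_randomisation"` (base case) or
#'   `"post_surgery"`.
#' @param rescale rescale QALYs to the nominal 730-day span.
#' @param perspective cost perspective (societal base case).
#' @param cost_discount_rate annual rate applied to second-year cost
#'   components (set 0 to disable).
#' @param qaly_discount_rate annual rate applied to QALYs (0 = undiscounted,
#'   the within-trial default; the ten-year model discounts both).
#' @param covariates adjustment covariates.
#' @param B bootstrap resamples.
#' @param lambda willingness-to-pay grid for the CEAC.
#' @param seed optional seed for the bootstrap.
#' @return object of class `cea_result`: the `sur_ce` fit, bootstrap `draws`,
#'   `ceac` points, `icer` classification, per-arm `estimates` and
#'   `incrementals` with percentile CIs, and the settings used.
#' @export
cea_within_trial <- function(trial,
                             unit_costs = default_unit_costs(),
                             cpi = default_cpi(), target_year = 2017,
                             tariff = toy_tariff(),
                             analysis = c("post_randomisation", "post_surgery"),
                             rescale = FALSE,
                             perspective = "societal",
                             cost_discount_rate = 0.035,
                             qaly_discount_rate = 0,
                             covariates = c("stratum", "baseline_utility"),
                             B = 1000,
                             lambda = c(0, 10000, 20000, 30000, 50000),
                             seed = NULL) {
  analysis <- match.arg(analysis)
  costs <- cost_patients(trial, unit_costs, cpi, target_year,
                         discount_rate = cost_discount_rate)
  qalys <- compute_qalys(trial, tariff, analysis, rescale = rescale,
                         discount_rate = qaly_discount_rate)
  frame <- build_analysis_frame(trial, costs, qalys, perspective, tariff)
  fit <- sur_adjusted_increments(frame, covariates)
  draws <- bootstrap_ce(frame, B = B,
                        seed = seed %||% stage_seed(trial$seed %||% 1, "bootstrap"),
                        covariates = covariates)
  cc <- ceac(draws, lambda)
  icer <- classify_icer(fit$delta_cost, fit$delta_qaly)

  ci <- function(x) unname(quantile(x, c(0.025, 0.975)))
  est <- fit$adjusted_means
  est$cost_low <- c(ci(draws$cost_intervention)[1], ci(draws$cost_comparator)[1])
  est$cost_high <- c(ci(draws$cost_intervention)[2], ci(draws$cost_comparator)[2])
  est$qaly_low <- c(ci(draws$qaly_intervention)[1], ci(draws$qaly_comparator)[1])
  est$qaly_high <- c(ci(draws$qaly_intervention)[2], ci(draws$qaly_comparator)[2])
  est$n <- c(fit$n_per_arm[[fit$intervention]], fit$n_per_arm[[fit$comparator]])

  incr <- tibble(
    term = c("delta_cost", "delta_qaly"),
    estimate = c(fit$delta_cost, fit$delta_qaly),
    conf.low = c(ci(draws$delta_cost)[1], ci(draws$delta_qaly)[1]),
    conf.high = c(ci(draws$delta_cost)[2], ci(draws$delta_qaly)[2])
  )

  structure(
    list(
      fit = fit, draws = draws, ceac = cc, icer = icer,
      estimates = est, incrementals = incr, frame = frame,
      settings = list(analysis = analysis, rescale = rescale,
                      perspective = perspective, B = B, lambda = lambda,
                      cost_discount_rate = cost_discount_rate,
                      qaly_discount_rate = qaly_discount_rate)
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  s <- x$settings
  cat("<cea_result>", s$analysis, if (s$rescale) "(rescaled QALY)" else "",
      "n =", x$fit$n, "\n")
  cat(sprintf("  incremental cost %.0f (%.0f, %.0f); incremental QALY %.3f (%.3f, %.3f)\n",
              x$incrementals$estimate[1], x$incrementals$conf.low[1],
              x$incrementals$conf.high[1], x$incrementals$estimate[2],
              x$incrementals$conf.low[2], x$incrementals$conf.high[2]))
  lab <- x$icer$label
  cat("  intervention:",
      if (lab == "icer") sprintf("ICER %.0f per QALY", x$icer$icer) else lab, "\n")
  invisible(x)
}

#' Within-trial analysis under multiple imputation
#'
#' Completes the missing utilities `m` times with [impute_utilities()],
#' recomputes QALYs and refits the adjusted regression on every completed
#' dataset (all randomised participants), pools the incremental cost and QALY
#' with Rubin's rules, and stacks per-imputation bootstrap draws (about `B/m`
#' per completed dataset) for the acceptability curve. With no missing data
#' every completed dataset equals the observed one, so the pooled result
#' coincides with the complete-case analysis.
#'
#' @inheritParams cea_within_trial
#' @param m number of imputations.
#' @param k,iter PMM settings passed to [impute_utilities()].
#' @return object of class `mi_cea_result`: `pooled` (Rubin-pooled
#'   incrementals), `estimates` (pooled adjusted arm means), `per_imputation`,
#'   `draws`, `ceac`, `icer`.
#' @export
mi_cea <- function(trial,
                   unit_costs = default_unit_costs(),
                   cpi = default_cpi(), target_year = 2017,
                   tariff = toy_tariff(),
                   analysis = c("post_randomisation", "post_surgery"),
                   rescale = FALSE, perspective = "societal",
                   cost_discount_rate = 0.035, qaly_discount_rate = 0,
                   covariates = c("stratum", "baseline_utility"),
                   m = 25, k = 5, iter = 5, B = 1000,
                   lambda = c(0, 10000, 20000, 30000, 50000),
                   seed = NULL) {
  analysis <- match.arg(analysis)
  seed <- seed %||% stage_seed(trial$seed %||% 1, "impute")
  imp <- impute_utilities(trial, tariff, m = m, seed = seed, k = k,
                          iter = iter, unit_costs = unit_costs, cpi = cpi)
  costs <- cost_patients(trial, unit_costs, cpi, target_year,
                         discount_rate = cost_discount_rate)
  b_per <- if (B <= 0) 0 else max(ceiling(B / m), 50) # B = 0: point estimates only

  per <- vector("list", m)
  draw_sets <- vector("list", m)
  for (i in seq_len(m)) {
    tr_i <- trial
    tr_i$observations <- imp$completed[[i]]
    qalys <- compute_qalys(tr_i, tariff, analysis, rescale = rescale,
                           discount_rate = qaly_discount_rate)
    frame <- build_analysis_frame(tr_i, costs, qalys, perspective, tariff,
                                  complete_cases = FALSE) |>
      filter(!is.na(.data$qaly), !is.na(.data$cost),
             !is.na(.data$baseline_utility))
    fit <- sur_adjusted_increments(frame, covariates)
    per[[i]] <- tibble(
      imputation = i,
      delta_cost = fit$delta_cost, delta_qaly = fit$delta_qaly,
      var_delta_cost = fit$vcov_delta[1, 1],
      var_delta_qaly = fit$vcov_delta[2, 2],
      cost_intervention = fit$adjusted_means$cost[1],
      cost_comparator = fit$adjusted_means$cost[2],
      qaly_intervention = fit$adjusted_means$qaly[1],
      qaly_comparator = fit$adjusted_means$qaly[2],
      n = fit$n
    )
    # per-imputation resamples are stacked, so a small per-set B is intended
    if (b_per > 0) {
      draw_sets[[i]] <- suppressWarnings(
        bootstrap_ce(frame, B = b_per, seed = seed + i,
                     covariates = covariates))
    }
  }
  per <- list_rbind(per)
  draws <- if (b_per > 0) list_rbind(draw_sets) else NULL

  pooled <- bind_rows(
    pool_rubin(per$delta_cost, per$var_delta_cost) |>
      mutate(term = "delta_cost", .before = 1),
    pool_rubin(per$delta_qaly, per$var_delta_qaly) |>
      mutate(term = "delta_qaly", .before = 1)
  )
  estimates <- tibble(
    arm = c("urethroplasty", "urethrotomy"),
    cost = c(mean(per$cost_intervention), mean(per$cost_comparator)),
    qaly = c(mean(per$qaly_intervention), mean(per$qaly_comparator)),
    n = mean(per$n)
  )
  icer <- classify_icer(pooled$estimate[pooled$term == "delta_cost"],
                        pooled$estimate[pooled$term == "delta_qaly"])
  structure(
    list(pooled = pooled, estimates = estimates, per_imputation = per,
         draws = draws,
         ceac = if (!is.null(draws)) ceac(draws, lambda) else NULL,
         icer = icer,
         settings = list(analysis = analysis, rescale = rescale,
                         perspective = perspective, m = m, B = b_per * m,
                         lambda = lambda)),
    class = "mi_cea_result"
  )
}

#' @export
print.mi_cea_result <- function(x, ...) {
  cat("<mi_cea_result> m =", x$settings$m, "imputations,",
      x$settings$analysis, "\n")
  print(x$pooled[, c("term", "estimate", "conf.low", "conf.high")])
  invisible(x)
}
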