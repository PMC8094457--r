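format_money <- function(x) sprintf("%.0f", round_half_up(x, 0))
format_qaly <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Format a probability as a whole percentage
#'
#' Published acceptability tables print whole percentages rounded half up
#' (0.994 prints as "99", 0.995 as "100").
#'
#' @param p probability in `[0, 1]`.
#' @return character vector of whole percentages.
#' @export
format_percent <- function(p) {
  sprintf("%.0f", round_half_up(100 * p, 0))
}

fmt_ci <- function(x, lo, hi, fmt) {
  sprintf("%s (%s, %s)", fmt(x), fmt(lo), fmt(hi))
}

#' Render the total-cost table
#'
#' Mean (SD) total cost per arm for the three nested perspectives, one row
#' per perspective, mirroring the trial's cost table layout (costs to whole
#' pounds).
#'
#' @param costs output of [cost_patients()].
#' @param patients patient table with `id` and `arm_allocated`.
#' @return tibble of formatted strings.
#' @export
render_table1 <- function(costs, patients) {
  req <- c("cost_intervention", "cost_nhs", "cost_societal")
  if (!all(req %in% names(costs))) {
    abort(paste("`costs` is missing field(s):",
                paste(setdiff(req, names(costs)), collapse = ", ")))
  }
  df <- patients |>
    select("id", "arm_allocated") |>
    left_join(costs, by = "id") |>
    tidyr::pivot_longer(dplyr::all_of(req), names_to = "perspective",
                        values_to = "cost") |>
    group_by(.data$perspective, .data$arm_allocated) |>
    summarise(cell = sprintf("%s (%s)", format_money(mean(.data$cost)),
                             format_money(sd(.data$cost))),
              n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm_allocated",
                       values_from = c("cell", "n"))
  labels <- c(
    cost_intervention = "Total intervention and re-intervention cost",
    cost_nhs = "Total NHS cost (intervention and re-intervention with follow-up)",
    cost_societal = "Total societal cost (NHS and patient costs)"
  )
  df |>
    mutate(total_cost = labels[.data$perspective],
           .before = 1) |>
    arrange(match(.data$perspective, names(labels))) |>
    select("total_cost",
           urethroplasty = "cell_urethroplasty", n_urethroplasty = "n_urethroplasty",
           urethrotomy = "cell_urethrotomy", n_urethrotomy = "n_urethrotomy")
}

# Two formatted rows (intervention then comparator) for one analysis.
ce_result_rows <- function(res, analysis_label) {
  est <- if (inherits(res, "cea_result")) res$estimates else res$estimates
  if (is.null(est) || nrow(est) != 2) abort("Result lacks per-arm estimates.")
  icer <- res$icer
  if (nrow(res$ceac) == 0) abort("Result has an empty CEAC.")
  lam <- sort(unique(res$ceac$lambda))
  probs <- function(strategy) {
    p <- res$ceac |> filter(.data$strategy == !!strategy) |> arrange(.data$lambda)
    setNames(as.list(format_percent(p$probability)),
             paste0("p_wtp_", lam / 1000, "k"))
  }
  icer_cells <- switch(icer$label,
    dominated = c("", "Dominant"),
    dominant = c("Dominant", ""),
    icer = c(format_money(icer$icer), "")
  )
  if (inherits(res, "cea_result")) {
    inc <- res$incrementals
    cost_ci <- fmt_ci(est$cost, est$cost_low, est$cost_high, format_money)
    qaly_ci <- fmt_ci(est$qaly, est$qaly_low, est$qaly_high, format_qaly)
    inc_cost <- fmt_ci(inc$estimate[1], inc$conf.low[1], inc$conf.high[1],
                       format_money)
    inc_qaly <- fmt_ci(inc$estimate[2], inc$conf.low[2], inc$conf.high[2],
                       format_qaly)
    n <- est$n
  } else { # mi_cea_result
    pooled <- res$pooled
    cost_ci <- format_money(est$cost)
    qaly_ci <- format_qaly(est$qaly)
    inc_cost <- fmt_ci(pooled$estimate[1], pooled$conf.low[1],
                       pooled$conf.high[1], format_money)
    inc_qaly <- fmt_ci(pooled$estimate[2], pooled$conf.low[2],
                       pooled$conf.high[2], format_qaly)
    n <- rep(est$n, 2)
  }
  bind_rows(
    tibble(analysis = analysis_label, strategy = est$arm[1], n = n[1],
           cost = cost_ci[1], incremental_cost = inc_cost,
           qaly = qaly_ci[1], incremental_qaly = inc_qaly,
           icer = icer_cells[1], !!!probs(est$arm[1])),
    tibble(analysis = analysis_label, strategy = est$arm[2], n = n[2],
           cost = cost_ci[2], incremental_cost = "",
           qaly = qaly_ci[2], incremental_qaly = "",
           icer = icer_cells[2], !!!probs(est$arm[2]))
  )
}

#' Render the within-trial cost-effectiveness table
#'
#' One pair of strategy rows per analysis variant with adjusted means and
#' percentile CIs, incrementals, the ICER-or-dominance cell (the word
#' "Dominant" appears on the comparator's row when the intervention is
#' dominated), and CEAC probabilities at the willingness-to-pay thresholds
#' (costs to whole pounds, QALYs to 2 decimals, probabilities whole percent).
#'
#' @param results named list of `cea_result` / `mi_cea_result` objects; names
#'   become the analysis labels.
#' @return tibble of formatted strings.
#' @export
render_table3 <- function(results) {
  if (length(results) == 0) abort("No results to render.")
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("`results` must be a fully named list of analyses.")
  }
  list_rbind(imap(results, function(res, name) ce_result_rows(res, name)))
}

#' Render the Markov model table
#'
#' One pair of strategy rows per scenario with discounted cost (whole
#' pounds), QALY (2 decimals), ICER-or-dominance cell and, when present, CEAC
#' probability columns as whole percentages.
#'
#' @param scenarios output of [run_scenarios()].
#' @return tibble of formatted strings.
#' @export
render_table4 <- function(scenarios) {
  req <- c("analysis", "strategy", "cost", "qaly", "label", "icer")
  if (!all(req %in% names(scenarios))) {
    abort(paste("`scenarios` is missing field(s):",
                paste(setdiff(req, names(scenarios)), collapse = ", ")))
  }
  pcols <- grep("^p_wtp_", names(scenarios), value = TRUE)
  out <- scenarios |>
    group_by(.data$analysis) |>
    mutate(icer_cell = {
      lab <- .data$label[.data$strategy == "urethroplasty"]
      ic <- .data$icer[.data$strategy == "urethroplasty"]
      dplyr::case_when(
        lab == "dominated" & .data$strategy == "urethrotomy" ~ "Dominant",
        lab == "dominant" & .data$strategy == "urethroplasty" ~ "Dominant",
        lab == "icer" & .data$strategy == "urethroplasty" ~ format_money(ic),
        .default = ""
      )
    }) |>
    ungroup() |>
    mutate(cost = format_money(.data$cost), qaly = format_qaly(.data$qaly))
  for (pc in pcols) out[[pc]] <- format_percent(scenarios[[pc]])
  out |> select("analysis", "strategy", "cost", "qaly",
                icer = "icer_cell", dplyr::all_of(pcols))
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a trial, costs it, computes QALYs, runs the complete-case and
#' multiply-imputed within-trial analyses, the Markov scenarios and the PSA,
#' and writes every output as delimited text plus a `manifest.json` recording
#' seeds, problem sizes and package version. All randomness derives from the
#' single `seed`, so reruns with the same arguments are byte-identical (the
#' manifest's timestamp aside). Partial outputs are removed on failure.
#'
#' @param out_dir output directory.
#' @param seed root seed.
#' @param config a [sim_config()].
#' @param perspective cost perspective for the within-trial analysis.
#' @param B bootstrap resamples.
#' @param m imputations.
#' @param psa_draws PSA draws.
#' @param markov a [markov_spec()].
#' @param unit_costs,cpi,tariff inputs.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = sim_config(),
                         perspective = "societal", B = 1000, m = 10,
                         psa_draws = 1000, markov = default_markov_spec(),
                         unit_costs = default_unit_costs(),
                         cpi = default_cpi(), tariff = toy_tariff()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  config$seed <- seed
  trial <- simulate_trial(config, seed = seed, compute_truth = FALSE)
  write_trial_data(trial, out_dir)
  written <- c(written, file.path(out_dir, c(
    "patients.csv", "observations.csv", "resources.csv", "oop.csv",
    "reinterventions.csv", "config.yaml")))

  costs <- cost_patients(trial, unit_costs, cpi, discount_rate = 0.035)
  wcsv(costs, "costs.csv")
  wcsv(render_table1(costs, trial$patients), "table1.csv")

  cc <- cea_within_trial(trial, unit_costs, cpi, tariff = tariff,
                         perspective = perspective, B = B,
                         seed = stage_seed(seed, "bootstrap"))
  mi <- mi_cea(trial, unit_costs, cpi, tariff = tariff,
               perspective = perspective, m = m, B = B,
               seed = stage_seed(seed, "impute"))
  qalys <- compute_qalys(trial, tariff)
  wcsv(qalys, "qalys.csv")
  wcsv(render_table3(list(
    `Base case, 24 months post randomisation` = cc,
    `24 months post randomisation with imputation` = mi
  )), "table3.csv")
  wcsv(cc$ceac, "ceac_points.csv")
  wcsv(cc$draws, "ce_plane_draws.csv")

  scen <- run_scenarios(markov, psa_spec = function(s) default_psa_spec(s),
                        n_draws = psa_draws, seed = stage_seed(seed, "psa"))
  wcsv(render_table4(scen), "table4.csv")
  ps <- psa(markov, n_draws = psa_draws, seed = stage_seed(seed, "psa"))
  wcsv(ps$draws, "psa_draws.csv")
  wcsv(ps$ceac, "ceac_model.csv")

  manifest <- list(
    package = "urocea",
    version = as.character(packageVersion("urocea")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    stage_seeds = list(
      simulate = stage_seed(seed, "simulate"),
      missing = stage_seed(seed, "missing"),
      bootstrap = stage_seed(seed, "bootstrap"),
      impute = stage_seed(seed, "impute"),
      psa = stage_seed(seed, "psa")
    ),
    sizes = list(n_per_arm = config$n_per_arm, B = B, m = m,
                 psa_draws = psa_draws),
    perspective = perspective,
    outputs = basename(written)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
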