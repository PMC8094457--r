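#' Area-under-the-curve QALYs
#'
#' Trapezoidal integration of a utility time series over day offsets, divided
#' by the number of days per year, so one year in full health yields one QALY.
#'
#' @param days strictly increasing day offsets from the anchor, first at 0.
#' @param utilities utilities at those days (all `<= 1`).
#' @param days_per_year divisor converting day-areas to years (365.25).
#' @return QALYs accrued over the observed span.
#' @export
#' @examples
#' qaly_auc(c(0, 365.25), c(0.8, 0.6))
qaly_auc <- function(days, utilities, days_per_year = 365.25) {
  check_series(days, utilities)
  sum(diff(days) * (head(utilities, -1) + tail(utilities, -1)) / 2) /
    days_per_year
}

check_series <- function(days, utilities) {
  if (length(days) < 2) {
    abort("A utility series needs at least two points (area undefined).")
  }
  if (length(days) != length(utilities)) {
    abort("`days` and `utilities` must have equal length.")
  }
  if (any(diff(days) <= 0)) abort("`days` must be strictly increasing.")
  if (any(is.na(utilities)) || any(utilities > 1 + 1e-12)) {
    abort("Utilities must be non-missing and no greater than 1.")
  }
  invisible(TRUE)
}

#' Rescale a QALY to the nominal follow-up span
#'
#' Accounts for between-arm differences in waiting times by multiplying the
#' observed-span QALY by `nominal_days / observed_span_days` (identity when
#' the spans match). The nominal span is the trial's 730-day data collection
#' window.
#'
#' @param qaly QALY(s) over the observed span.
#' @param observed_span_days span of the observed series in days (> 0).
#' @param nominal_days nominal span (730).
#' @return rescaled QALY(s).
#' @export
rescale_qaly <- function(qaly, observed_span_days, nominal_days = 730) {
  if (any(observed_span_days <= 0)) {
    abort("`observed_span_days` must be positive.")
  }
  qaly * nominal_days / observed_span_days
}

#' Discounted area-under-the-curve QALYs
#'
#' As [qaly_auc()] but with each segment of the series weighted by the annual
#' discount factor of the year its midpoint falls in: the series is split at
#' year boundaries and a sub-segment with midpoint in year *k* (counting from
#' 0) is weighted by `(1 + rate)^-k`. Equal to the undiscounted AUC when
#' `rate = 0`.
#'
#' @inheritParams qaly_auc
#' @param rate annual discount rate (>= 0).
#' @return discounted QALYs.
#' @export
discount_qaly_series <- function(days, utilities, rate = 0.035,
                                 days_per_year = 365.25) {
  if (rate < 0) abort("`rate` must be non-negative.")
  check_series(days, utilities)
  bounds <- seq(days_per_year, max(days), by = days_per_year)
  cut_days <- sort(unique(c(days, bounds)))
  cut_days <- cut_days[cut_days >= min(days) & cut_days <= max(days)]
  u_cut <- stats::approx(days, utilities, xout = cut_days)$y
  a <- head(cut_days, -1); b <- tail(cut_days, -1)
  mid_year <- floor(((a + b) / 2) / days_per_year)
  areas <- (b - a) * (head(u_cut, -1) + tail(u_cut, -1)) / 2
  sum(areas * (1 + rate)^(-mid_year)) / days_per_year
}

#' Complete-case inclusion rules
#'
#' Flags whether each participant qualifies for the complete-case AUC
#' analysis. Participants who never received the index operation must have
#' complete EQ-5D-5L at baseline, 18 months and 24 months after randomisation
#' (both analyses). Operated participants need, for the
#' post-randomisation (base case) analysis, complete data at baseline and 24
#' months after randomisation plus at least one of the 3/6/9/12-months
#' post-surgery or 18-months post-randomisation points; for the post-surgery
#' analysis, complete data immediately prior to surgery and 24 months after
#' surgery plus at least one of the 3/6/9/12-months post-surgery or 18/24-
#' months post-randomisation points.
#'
#' @param trial a `uro_trial` (or list with `observations` and `patients`).
#' @param analysis `"post_randomisation"` or `"post_surgery"`.
#' @return tibble of `id`, `complete_case`.
#' @export
is_complete_case <- function(trial,
                             analysis = c("post_randomisation", "post_surgery")) {
  analysis <- match.arg(analysis)
  obs <- trial$observations
  # an observation counts as present when all five levels are recorded, or,
  # on an (imputed) utility-bearing table, when the utility is non-missing
  if ("utility" %in% names(obs)) {
    present <- obs |>
      filter(!is.na(.data$utility)) |>
      distinct(.data$id, .data$timepoint)
  } else {
    present <- obs |>
      mutate(observed =
               rowSums(is.na(pick(dplyr::all_of(eq5d_dimensions())))) == 0) |>
      filter(.data$observed) |>
      distinct(.data$id, .data$timepoint)
  }
  key <- function(tp) {
    unique(present$id[present$timepoint %in% tp])
  }
  all_of_tp <- function(tps) {
    Reduce(intersect, lapply(tps, function(t) key(t)))
  }
  pts <- trial$patients
  no_surg_ok <- all_of_tp(c("baseline", "m18_post_rand", "m24_post_rand"))
  if (analysis == "post_randomisation") {
    surg_ok <- intersect(all_of_tp(c("baseline", "m24_post_rand")),
                         key(midrange_post_rand()))
  } else {
    surg_ok <- intersect(all_of_tp(c("pre_surgery", "m24_post_surgery")),
                         key(midrange_post_surgery()))
  }
  tibble(
    id = pts$id,
    complete_case = ifelse(pts$had_index_surgery,
                           pts$id %in% surg_ok,
                           pts$id %in% no_surg_ok)
  )
}

#' Assemble per-patient utility time series
#'
#' Scores observations with the tariff, anchors each participant's series at
#' day 0 (randomisation/baseline, or the pre-surgery assessment date for the
#' post-surgery analysis; participants without surgery are always anchored at
#' randomisation), drops observations before the anchor, truncates offsets
#' beyond `max_days` to `max_days` (keeping the earliest observation at each
#' resulting offset), and returns the long table of usable points.
#'
#' @param trial a `uro_trial`.
#' @param tariff an [eq5d_tariff()].
#' @param anchor `"randomisation"` or `"surgery"`.
#' @param max_days window bound in days from the anchor.
#' @return tibble of `id`, `day` (offset from anchor), `utility`.
#' @export
build_utility_series <- function(trial, tariff = toy_tariff(),
                                 anchor = c("randomisation", "surgery"),
                                 max_days = 760) {
  anchor <- match.arg(anchor)
  obs <- trial$observations
  if (!"utility" %in% names(obs)) obs <- add_utilities(obs, tariff)
  obs <- filter(obs, !is.na(.data$utility))
  pts <- trial$patients
  anchor_day <- rep(0, nrow(pts))
  if (anchor == "surgery") {
    pre <- trial$observations |>
      filter(.data$timepoint == "pre_surgery") |>
      select("id", pre_day = "day")
    anchor_day <- ifelse(
      pts$had_index_surgery,
      pre$pre_day[match(pts$id, pre$id)],
      0
    )
  }
  obs |>
    mutate(offset = .data$day - anchor_day[match(.data$id, pts$id)]) |>
    filter(!is.na(.data$offset), .data$offset >= 0) |>
    mutate(offset = pmin(.data$offset, max_days)) |>
    arrange(.data$id, .data$day) |>
    distinct(.data$id, .data$offset, .keep_all = TRUE) |>
    transmute(id = .data$id, day = .data$offset, utility = .data$utility)
}

#' Per-patient QALYs for an analysis variant
#'
#' Builds each participant's utility series for the chosen analysis window,
#' integrates it (optionally with annual discounting), and optionally rescales
#' to the nominal 730-day span. The complete-case flag of the matching
#' inclusion rule set is attached; participants with fewer than two usable
#' points get `NA` QALYs.
#'
#' @param trial a `uro_trial`.
#' @param tariff an [eq5d_tariff()].
#' @param analysis `"post_randomisation"` (anchored at baseline) or
#'   `"post_surgery"` (anchored at the pre-surgery assessment).
#' @param rescale rescale to `nominal_days`.
#' @param nominal_days nominal span for rescaling.
#' @param discount_rate annual discount rate for QALYs (0 = undiscounted).
#' @param days_per_year days per year.
#' @return tibble of `id`, `n_obs`, `span_days`, `qaly`, `complete_case`.
#' @export
compute_qalys <- function(trial, tariff = toy_tariff(),
                          analysis = c("post_randomisation", "post_surgery"),
                          rescale = FALSE, nominal_days = 730,
                          discount_rate = 0, days_per_year = 365.25) {
  analysis <- match.arg(analysis)
  anchor <- if (analysis == "post_surgery") "surgery" else "randomisation"
  series <- build_utility_series(trial, tariff, anchor)
  per <- series |>
    group_by(.data$id) |>
    summarise(
      n_obs = dplyr::n(),
      span_days = max(.data$day),
      qaly = if (dplyr::n() < 2) NA_real_ else if (discount_rate > 0) {
        discount_qaly_series(.data$day, .data$utility, discount_rate,
                             days_per_year)
      } else {
        qaly_auc(.data$day, .data$utility, days_per_year)
      },
      .groups = "drop"
    )
  if (rescale) {
    ok <- !is.na(per$qaly) & per$span_days > 0
    per$qaly[ok] <- rescale_qaly(per$qaly[ok], per$span_days[ok], nominal_days)
    per$qaly[!ok] <- NA_real_
  }
  cc <- is_complete_case(trial, analysis)
  trial$patients["id"] |>
    left_join(per, by = "id") |>
    left_join(cc, by = "id") |>
    mutate(n_obs = dplyr::coalesce(.data$n_obs, 0L))
}
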