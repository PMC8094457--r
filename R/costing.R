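#' Unit cost and CPI tables
#'
#' Unit costs are an external input: a table of `item`, `unit`, `unit_cost`
#' and `price_year`. Prices from different years are converted to a common
#' target year (default 2017) with a consumer price index table of `year` and
#' `index`. The packaged defaults are illustrative fixtures, not national
#' reference costs.
#'
#' @param path delimited file path.
#' @return a tibble.
#' @export
read_unit_costs <- function(path) {
  uc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("item", "unit", "unit_cost", "price_year")
  if (!all(req %in% names(uc))) {
    abort(paste("Unit cost table needs columns:", paste(req, collapse = ", ")))
  }
  if (any(uc$unit_cost < 0)) abort("Unit costs must be non-negative.")
  if (anyDuplicated(uc$item)) abort("Each item must appear exactly once.")
  uc
}

#' @rdname read_unit_costs
#' @export
read_cpi <- function(path) {
  cpi <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("year", "index") %in% names(cpi))) {
    abort("CPI table needs columns `year` and `index`.")
  }
  if (any(cpi$index <= 0)) abort("CPI index values must be strictly positive.")
  cpi
}

#' @rdname read_unit_costs
#' @export
default_unit_costs <- function() {
  read_unit_costs(system.file("extdata", "unit_costs.csv", package = "urocea"))
}

#' @rdname read_unit_costs
#' @export
default_cpi <- function() {
  read_cpi(system.file("extdata", "cpi.csv", package = "urocea"))
}

#' Convert an amount between price years
#'
#' Multiplies by the ratio of CPI index values: `amount * cpi[target] /
#' cpi[from]`. The identity holds when the years are equal, and conversion is
#' transitive across intermediate years.
#'
#' @param amount money amount(s).
#' @param from_year price year(s) of `amount`.
#' @param cpi CPI tibble from [read_cpi()].
#' @param target_year target price year.
#' @return amount(s) expressed in target-year prices.
#' @export
#' @examples
#' cpi <- tibble::tibble(year = c(2015, 2017), index = c(98.0, 102.9))
#' adjust_price_year(100, 2015, cpi, 2017)
adjust_price_year <- function(amount, from_year, cpi, target_year = 2017) {
  idx <- setNames(cpi$index, cpi$year)
  missing_years <- setdiff(unique(c(from_year, target_year)), cpi$year)
  if (length(missing_years) > 0) {
    abort(paste("CPI index has no entry for year(s):",
                paste(missing_years, collapse = ", ")))
  }
  amount * unname(idx[as.character(target_year)]) /
    unname(idx[as.character(from_year)])
}

# Join resource rows to priced items; errors list every unpriced item.
cost_resource_rows <- function(resources, unit_costs, cpi, target_year = 2017) {
  unknown <- setdiff(unique(resources$item), unit_costs$item)
  if (length(unknown) > 0) {
    abort(paste("No unit cost for item(s):", paste(sort(unknown), collapse = ", ")))
  }
  resources |>
    left_join(unit_costs[, c("item", "unit_cost", "price_year")], by = "item") |>
    mutate(cost = adjust_price_year(.data$quantity * .data$unit_cost,
                                    .data$price_year, cpi, target_year))
}

#' Micro-cost of one or more procedures
#'
#' Sums quantity times unit cost over the itemised resource rows of a
#' procedure record (staff and theatre minutes, consumables, bed-days),
#' converting each item's price year to the target year. Deterministic and
#' linear in quantities.
#'
#' @param resources tibble with `item` and `quantity` (and optionally `id`,
#'   `day`).
#' @param unit_costs unit cost tibble.
#' @param cpi CPI tibble.
#' @param target_year price year of the result.
#' @return total cost (scalar).
#' @export
#' @examples
#' uc <- tibble::tibble(item = c("theatre_minute", "bed_day"),
#'                      unit = c("per minute", "per day"),
#'                      unit_cost = c(10, 300), price_year = 2017)
#' cpi <- tibble::tibble(year = 2017, index = 102.9)
#' procedure_cost(tibble::tibble(item = c("theatre_minute", "bed_day"),
#'                               quantity = c(90, 1.34)), uc, cpi)
procedure_cost <- function(resources, unit_costs, cpi = default_cpi(),
                           target_year = 2017) {
  if (nrow(resources) == 0) return(0)
  sum(cost_resource_rows(resources, unit_costs, cpi, target_year)$cost)
}

#' Per-patient cost breakdown
#'
#' Micro-costs every patient's index procedure, re-interventions (costed by
#' the same process as the index procedure), follow-up NHS contacts, and
#' out-of-pocket items, all expressed in target-year prices. Costs attach to
#' recall periods rather than calendar dates and are not rescaled across
#' follow-up; an optional annual discount rate down-weights second-year
#' components (rows with `day >= 365.25`), the trial-analysis default being
#' applied by [cea_within_trial()].
#'
#' Perspectives nest by construction: `cost_intervention` (index plus
#' re-intervention) `<= cost_nhs` (plus follow-up) `<= cost_societal` (plus
#' out-of-pocket).
#'
#' @param trial a `uro_trial`.
#' @param unit_costs,cpi,target_year pricing inputs.
#' @param discount_rate annual discount rate applied to second-year
#'   components (0 disables discounting).
#' @param days_per_year days per year used to assign rows to years.
#' @return tibble with one row per patient: component costs
#'   (`index_cost`, `reintervention_cost`, `followup_cost`, `oop_cost`) and
#'   perspective totals (`cost_intervention`, `cost_nhs`, `cost_societal`).
#' @export
cost_patients <- function(trial, unit_costs = default_unit_costs(),
                          cpi = default_cpi(), target_year = 2017,
                          discount_rate = 0, days_per_year = 365.25) {
  stopifnot(inherits(trial, "uro_trial"))
  assert_nonneg(discount_rate, "discount_rate")
  rows <- cost_resource_rows(trial$resources, unit_costs, cpi, target_year)
  disc <- function(day) (1 + discount_rate)^(-floor(day / days_per_year))
  rows$cost <- rows$cost * disc(rows$day)

  comp <- rows |>
    group_by(.data$id, .data$phase) |>
    summarise(cost = sum(.data$cost), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "cost",
                       values_fill = 0)
  for (ph in c("index", "reintervention", "followup")) {
    if (!ph %in% names(comp)) comp[[ph]] <- 0
  }
  oop <- trial$oop |>
    mutate(cost = .data$amount * disc(.data$day)) |>
    group_by(.data$id) |>
    summarise(oop = sum(.data$cost), .groups = "drop")

  trial$patients["id"] |>
    left_join(comp, by = "id") |>
    left_join(oop, by = "id") |>
    mutate(across(c("index", "reintervention", "followup", "oop"),
                  ~ dplyr::coalesce(.x, 0))) |>
    transmute(
      id = .data$id,
      index_cost = .data$index,
      reintervention_cost = .data$reintervention,
      followup_cost = .data$followup,
      oop_cost = .data$oop,
      cost_intervention = .data$index + .data$reintervention,
      cost_nhs = .data$cost_intervention + .data$followup,
      cost_societal = .data$cost_nhs + .data$oop
    )
}

#' Select a costing perspective
#'
#' @param costs output of [cost_patients()].
#' @param perspective one of `"intervention"` (index and re-intervention
#'   only), `"nhs"` (plus follow-up NHS contacts) or `"societal"` (plus
#'   patients' out-of-pocket costs).
#' @return tibble of `id`, `cost`.
#' @export
total_cost <- function(costs,
                       perspective = c("societal", "nhs", "intervention")) {
  if (length(perspective) == 1 &&
      !perspective %in% c("societal", "nhs", "intervention")) {
    abort(sprintf("Unknown perspective `%s`.", perspective))
  }
  perspective <- match.arg(perspective)
  col <- paste0("cost_", perspective)
  tibble(id = costs$id, cost = costs[[col]])
}
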