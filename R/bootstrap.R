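#' Bootstrap the joint distribution of incremental cost and QALY
#'
#' Non-parametric bootstrap stratified by arm (each resample redraws
#' participants with replacement within arm, preserving arm sizes, so no
#' resample can empty an arm), refitting the adjusted regression each time.
#' Besides the increments, the adjusted arm means at the grand covariate means
#' are recorded per draw so percentile intervals can be formed for every
#' reported quantity.
#'
#' @inheritParams sur_adjusted_increments
#' @param B number of bootstrap resamples (a warning is issued below 100).
#' @param seed optional seed; fixed seeds reproduce draws exactly.
#' @return tibble with one row per draw: `draw`, `delta_cost`, `delta_qaly`,
#'   `cost_intervention`, `cost_comparator`, `qaly_intervention`,
#'   `qaly_comparator`.
#' @export
bootstrap_ce <- function(frame, B = 1000, seed = NULL,
                         covariates = c("stratum", "baseline_utility"),
                         intervention = "urethroplasty",
                         comparator = "urethrotomy") {
  if (B < 100) warn("Fewer than 100 bootstrap resamples; CEAC and percentile CIs will be unstable.")
  if (!is.null(seed)) set.seed(seed)
  x <- frame_design(frame, covariates, intervention)
  check_full_rank(x)
  y <- cbind(frame$cost, frame$qaly)
  idx_int <- which(frame$arm == intervention)
  idx_comp <- which(frame$arm == comparator)
  k <- ncol(x)

  out <- matrix(NA_real_, nrow = B, ncol = 6)
  for (b in seq_len(B)) {
    i <- c(sample(idx_int, length(idx_int), replace = TRUE),
           sample(idx_comp, length(idx_comp), replace = TRUE))
    xb <- x[i, , drop = FALSE]
    fit <- lm.fit(xb, y[i, , drop = FALSE])
    cf <- fit$coefficients
    if (anyNA(cf)) cf[is.na(cf)] <- 0 # rare degenerate resample: aliased column
    xbar <- colMeans(xb)
    x0 <- xbar; x0[2] <- 0
    x1 <- xbar; x1[2] <- 1
    m <- rbind(x1, x0) %*% cf
    out[b, ] <- c(cf[2, 1], cf[2, 2], m[1, 1], m[2, 1], m[1, 2], m[2, 2])
  }
  tibble(
    draw = seq_len(B),
    delta_cost = out[, 1], delta_qaly = out[, 2],
    cost_intervention = out[, 3], cost_comparator = out[, 4],
    qaly_intervention = out[, 5], qaly_comparator = out[, 6]
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability a strategy is
#' cost-effective is the fraction of draws in which it has the highest net
#' monetary benefit (`lambda * effect - cost`). With two strategies the
#' intervention wins a draw exactly when `lambda * delta_qaly - delta_cost >
#' 0` (at `lambda = 0`, when it is cheaper), and the two probabilities sum to
#' 1 at every threshold.
#'
#' @param draws tibble with columns `delta_cost`, `delta_qaly` (bootstrap or
#'   probabilistic sensitivity draws of intervention minus comparator).
#' @param lambda willingness-to-pay thresholds (GBP per QALY).
#' @param intervention,comparator strategy labels.
#' @return tibble of `lambda`, `strategy`, `probability`.
#' @export
#' @examples
#' d <- tibble::tibble(delta_cost = c(1000, 1000), delta_qaly = c(0.1, -0.1))
#' ceac(d, lambda = c(0, 20000))
ceac <- function(draws, lambda = c(0, 10000, 20000, 30000, 50000),
                 intervention = "urethroplasty",
                 comparator = "urethrotomy") {
  if (is.null(draws) || nrow(draws) == 0) {
    abort("`draws` is empty; nothing to summarise.")
  }
  p_int <- vapply(lambda, function(l) {
    mean(l * draws$delta_qaly - draws$delta_cost > 0)
  }, numeric(1))
  bind_rows(
    tibble(lambda = lambda, strategy = intervention, probability = p_int),
    tibble(lambda = lambda, strategy = comparator, probability = 1 - p_int)
  ) |>
    arrange(.data$lambda, .data$strategy)
}
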