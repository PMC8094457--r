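#' Analysis frame for the within-trial cost-utility analysis
#'
#' One row per analysed participant with the chosen cost perspective and QALY
#' variant plus the adjustment covariates: allocated arm, the minimisation
#' stratum (time since last procedure < 12 months) and baseline utility.
#'
#' @param trial a `uro_trial`.
#' @param costs output of [cost_patients()].
#' @param qalys output of [compute_qalys()].
#' @param perspective cost perspective passed to [total_cost()].
#' @param tariff tariff used to score baseline utility.
#' @param complete_cases keep only participants with a complete-case QALY,
#'   non-missing cost and non-missing baseline utility.
#' @return tibble of `id`, `arm`, `stratum`, `baseline_utility`, `cost`,
#'   `qaly`, `complete_case`.
#' @export
build_analysis_frame <- function(trial, costs, qalys,
                                 perspective = "societal",
                                 tariff = toy_tariff(),
                                 complete_cases = TRUE) {
  obs <- trial$observations
  if (!"utility" %in% names(obs)) obs <- add_utilities(obs, tariff)
  base_u <- obs |>
    filter(.data$timepoint == "baseline") |>
    select("id", baseline_utility = "utility")
  frame <- trial$patients |>
    select("id", arm = "arm_allocated", "stratum") |>
    left_join(base_u, by = "id") |>
    left_join(total_cost(costs, perspective), by = "id") |>
    left_join(qalys[, c("id", "qaly", "complete_case")], by = "id") |>
    mutate(complete_case = .data$complete_case &
             !is.na(.data$qaly) & !is.na(.data$cost) &
             !is.na(.data$baseline_utility))
  if (complete_cases) frame <- filter(frame, .data$complete_case)
  frame
}

# Design matrix shared by the point fit and the bootstrap. The arm indicator
# is always the second column.
frame_design <- function(frame, covariates, intervention) {
  x <- cbind(`(Intercept)` = 1,
             arm = as.numeric(frame$arm == intervention))
  for (cv in covariates) {
    v <- frame[[cv]]
    if (is.null(v)) abort(sprintf("Covariate `%s` not found in frame.", cv))
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      mm <- model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(v)[-1])
      x <- cbind(x, mm)
    } else {
      x <- cbind(x, setNames(data.frame(v), cv) |> as.matrix())
    }
  }
  x
}

check_full_rank <- function(x) {
  q <- qr(x)
  if (q$rank < ncol(x)) {
    bad <- colnames(x)[q$pivot[(q$rank + 1):ncol(x)]]
    abort(paste("Design matrix is singular; collinear column(s):",
                paste(bad, collapse = ", ")))
  }
  invisible(q)
}

#' Covariate-adjusted incremental cost and QALY
#'
#' Jointly regresses cost and QALY on identical regressors (allocated arm plus
#' adjustment covariates), the seemingly-unrelated-regression system of the
#' within-trial analysis. With identical regressors in both equations the
#' coefficient estimates coincide with per-equation least squares; the joint
#' coefficient covariance uses the cross-equation residual covariance, so the
#' correlation between the cost and QALY increments is carried downstream.
#' Adjusted arm means are evaluated at the grand covariate means, so they
#' differ by exactly the arm coefficient.
#'
#' @param frame an analysis frame from [build_analysis_frame()] with at least
#'   two participants per arm and no missing covariates.
#' @param covariates names of adjustment covariates (character/factor columns
#'   are expanded to indicators). The trial analysis adjusts for the
#'   dichotomised time-since-last-procedure stratum and baseline utility.
#' @param intervention,comparator arm labels; increments are
#'   intervention minus comparator.
#' @return object of class `sur_ce` with elements `delta_cost`, `delta_qaly`,
#'   `vcov_delta` (2x2 covariance of the increments), `adjusted_means`,
#'   `coefficients`, `sigma` (residual covariance), `n`.
#' @export
sur_adjusted_increments <- function(frame,
                                    covariates = c("stratum", "baseline_utility"),
                                    intervention = "urethroplasty",
                                    comparator = "urethrotomy") {
  if (any(is.na(frame$cost)) || any(is.na(frame$qaly))) {
    abort("Frame has missing outcomes; restrict to complete cases first.")
  }
  n_arm <- table(frame$arm)
  if (length(n_arm) < 2 || any(n_arm < 2)) {
    abort("Need at least two participants per arm.")
  }
  x <- frame_design(frame, covariates, intervention)
  check_full_rank(x)
  y <- cbind(cost = frame$cost, qaly = frame$qaly)
  fit <- lm.fit(x, y)
  k <- ncol(x); n <- nrow(x)
  resid <- y - x %*% fit$coefficients
  sigma <- crossprod(resid) / (n - k)
  xtxinv <- chol2inv(chol(crossprod(x)))
  vcov_full <- kronecker(sigma, xtxinv,
                         make.dimnames = FALSE)
  arm_row <- 2L
  idx <- c(arm_row, k + arm_row)
  vcov_delta <- vcov_full[idx, idx]
  dimnames(vcov_delta) <- list(c("delta_cost", "delta_qaly"),
                               c("delta_cost", "delta_qaly"))

  xbar <- colMeans(x)
  x0 <- xbar; x0[arm_row] <- 0
  x1 <- xbar; x1[arm_row] <- 1
  adj <- rbind(x1, x0) %*% fit$coefficients
  adjusted_means <- tibble(
    arm = c(intervention, comparator),
    cost = adj[, "cost"], qaly = adj[, "qaly"]
  )

  structure(
    list(
      coefficients = fit$coefficients,
      delta_cost = unname(fit$coefficients[arm_row, "cost"]),
      delta_qaly = unname(fit$coefficients[arm_row, "qaly"]),
      vcov_delta = vcov_delta,
      sigma = sigma,
      adjusted_means = adjusted_means,
      n = n, n_per_arm = as.list(n_arm),
      covariates = covariates,
      intervention = intervention, comparator = comparator
    ),
    class = "sur_ce"
  )
}

#' @export
print.sur_ce <- function(x, ...) {
  cat("<sur_ce> n =", x$n, "\n")
  cat(sprintf("  incremental cost: %.2f (se %.2f)\n",
              x$delta_cost, sqrt(x$vcov_delta[1, 1])))
  cat(sprintf("  incremental QALY: %.4f (se %.4f)\n",
              x$delta_qaly, sqrt(x$vcov_delta[2, 2])))
  invisible(x)
}
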