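#' Multiple imputation of EQ-5D-5L utilities by chained equations
#'
#' Imputes missing utilities at the scheduled-timepoint level with predictive
#' mean matching (PMM) in a chained-equations sweep, after which QALYs can be
#' recomputed on every completed dataset. Predictors for each timepoint's
#' utility are allocated arm, the minimisation stratum, baseline utility, the
#' adjacent timepoints' (current) utilities and the total observed cost.
#' Observed values are never altered, so the `m` completed datasets agree on
#' them and differ only at imputed cells. PMM draws regression coefficients
#' from their posterior and then borrows an observed value from one of the `k`
#' donors whose predicted utility is nearest, so imputed values are always
#' observed utilities.
#'
#' Only EQ-5D-5L utilities are imputable; costs and covariates must be
#' complete. A timepoint with every scheduled value missing cannot be imputed
#' and raises an error.
#'
#' @param trial a `uro_trial` with missing EQ-5D-5L observations.
#' @param tariff tariff used to score the observed profiles.
#' @param m number of imputations (>= 2).
#' @param seed optional seed.
#' @param k number of PMM donors.
#' @param iter chained-equation sweeps per imputation.
#' @param unit_costs,cpi pricing inputs for the total-cost predictor.
#' @return an object of class `uro_mi`: list with `completed` (a list of `m`
#'   observation tables carrying a completed `utility` column and an
#'   `imputed` flag) plus the settings.
#' @export
impute_utilities <- function(trial, tariff = toy_tariff(), m = 25,
                             seed = NULL, k = 5, iter = 5,
                             unit_costs = default_unit_costs(),
                             cpi = default_cpi()) {
  stopifnot(inherits(trial, "uro_trial"))
  if (m < 2) abort("Multiple imputation needs m >= 2 imputations.")
  if (!is.null(seed)) set.seed(seed)

  obs <- add_utilities(trial$observations, tariff)
  tps <- eq5d_timepoints()
  pts <- trial$patients
  n <- nrow(pts)

  # wide utility matrix; cells that are never scheduled stay structurally NA
  u <- matrix(NA_real_, n, length(tps), dimnames = list(NULL, tps))
  row_of <- match(obs$id, pts$id)
  col_of <- match(obs$timepoint, tps)
  u[cbind(row_of, col_of)] <- obs$utility
  scheduled <- matrix(FALSE, n, length(tps))
  scheduled[cbind(row_of, col_of)] <- TRUE
  miss <- scheduled & is.na(u)

  target_cols <- which(colSums(miss) > 0)
  for (j in target_cols) {
    if (!any(scheduled[, j] & !miss[, j])) {
      abort(sprintf("Every scheduled value of `%s` is missing; cannot impute.",
                    tps[j]))
    }
  }

  covars <- cbind(
    arm = as.numeric(pts$arm_allocated == "urethroplasty"),
    stratum = as.numeric(pts$stratum == "lt12m"),
    cost = cost_patients(trial, unit_costs, cpi)$cost_societal / 1000
  )

  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    uf <- u
    for (j in target_cols) { # initial fill: random observed values
      donors <- uf[scheduled[, j] & !miss[, j], j]
      uf[miss[, j], j] <- sample(donors, sum(miss[, j]), replace = TRUE)
    }
    if (length(target_cols) > 0) {
      for (it in seq_len(iter)) {
        for (j in target_cols) {
          z <- impute_predictors(uf, j, covars)
          oi <- which(scheduled[, j] & !miss[, j])
          mi <- which(miss[, j])
          uf[mi, j] <- pmm_draw(uf[oi, j], z[oi, , drop = FALSE],
                                z[mi, , drop = FALSE], k)
        }
      }
    }
    out <- obs
    out$utility <- uf[cbind(row_of, col_of)]
    out$imputed <- miss[cbind(row_of, col_of)]
    completed[[imp]] <- out
  }
  structure(list(completed = completed, m = m, k = k, iter = iter),
            class = "uro_mi")
}

# Predictor matrix for timepoint column j: intercept, covariates, baseline
# utility and the adjacent columns (current fill). Structural gaps in a
# predictor column are replaced by its mean.
impute_predictors <- function(uf, j, covars) {
  cols <- unique(c(1L, j - 1L, j + 1L))
  cols <- setdiff(cols[cols >= 1 & cols <= ncol(uf)], j)
  z <- cbind(1, covars, uf[, cols, drop = FALSE])
  for (c_ in seq_len(ncol(z))) {
    bad <- is.na(z[, c_])
    if (any(bad)) z[bad, c_] <- mean(z[, c_], na.rm = TRUE)
  }
  z
}

# One PMM draw: Bayesian regression parameter draw, nearest-donor matching.
pmm_draw <- function(y_obs, z_obs, z_mis, k) {
  q <- qr(z_obs)
  keep <- q$pivot[seq_len(q$rank)]
  zo <- z_obs[, keep, drop = FALSE]
  zm <- z_mis[, keep, drop = FALSE]
  fit <- lm.fit(zo, y_obs)
  beta <- fit$coefficients
  res <- y_obs - zo %*% beta
  df <- length(y_obs) - length(beta)
  if (df > 0) {
    sigma2 <- sum(res^2) / rchisq(1, df)
    r <- chol(crossprod(zo))
    beta_draw <- beta + backsolve(r, rnorm(length(beta))) * sqrt(sigma2)
  } else {
    beta_draw <- beta
  }
  yhat_obs <- drop(zo %*% beta)
  yhat_mis <- drop(zm %*% beta_draw)
  vapply(yhat_mis, function(p) {
    d <- abs(yhat_obs - p)
    kk <- min(k, length(d))
    donors <- order(d)[seq_len(kk)]
    y_obs[donors[sample.int(kk, 1)]]
  }, numeric(1))
}
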