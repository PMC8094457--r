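#' Pool estimates across imputations with Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance; the confidence interval uses a t reference
#' with Rubin's degrees of freedom (infinite when the between-imputation
#' variance is zero).
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param variances per-imputation squared standard errors (same length).
#' @param conf_level confidence level.
#' @return one-row tibble: `estimate`, `se`, `df`, `conf.low`, `conf.high`,
#'   `riv` (relative increase in variance), `m`.
#' @export
#' @examples
#' pool_rubin(c(1, 3), c(1, 1))
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) abort("Rubin pooling needs at least two imputations.")
  if (length(variances) != m) {
    abort("`estimates` and `variances` must have the same length.")
  }
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- var(estimates)
  total <- w + (1 + 1 / m) * b
  if (b > 0 && w > 0) {
    riv <- (1 + 1 / m) * b / w
    df <- (m - 1) * (1 + 1 / riv)^2
  } else {
    riv <- 0
    df <- Inf
  }
  se <- sqrt(total)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  tibble(
    estimate = qbar, se = se, df = df,
    conf.low = qbar - tcrit * se, conf.high = qbar + tcrit * se,
    riv = riv, m = m
  )
}
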