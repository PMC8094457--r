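#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables round half up, so a
#' probability of 0.994 prints as 99% and 0.995 as 100%.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stage-specific seed from a single root seed so every stage of a
# pipeline is independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, missing = 23L, truth = 37L, bootstrap = 53L,
    impute = 71L, psa = 89L, markov = 97L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 2000000L) * 1000L + off
}

# Gamma draws parameterised by mean and sd; sd = 0 gives the mean exactly.
rgamma_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

# Poisson counts with a degenerate switch: sd = 0 returns the mean as a
# deterministic (possibly fractional) quantity, used by no-noise configs.
rcount_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  rpois(n, lambda = mean)
}

other_arm <- function(arm) {
  ifelse(arm == "urethroplasty", "urethrotomy", "urethroplasty")
}

assert_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}
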