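#' Tidiers for fitted objects
#'
#' Broom-style `tidy()` and `glance()` methods so results drop into pipelines.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return a tibble.
#' @name urocea-tidiers
NULL

#' @rdname urocea-tidiers
#' @export
tidy.sur_ce <- function(x, ...) {
  cf <- x$coefficients
  bind_rows(
    tibble(equation = "cost", term = rownames(cf), estimate = cf[, "cost"]),
    tibble(equation = "qaly", term = rownames(cf), estimate = cf[, "qaly"])
  )
}

#' @rdname urocea-tidiers
#' @export
glance.sur_ce <- function(x, ...) {
  tibble(
    n = x$n,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    se_delta_cost = sqrt(x$vcov_delta[1, 1]),
    se_delta_qaly = sqrt(x$vcov_delta[2, 2]),
    resid_correlation = x$sigma[1, 2] / sqrt(x$sigma[1, 1] * x$sigma[2, 2])
  )
}

#' @rdname urocea-tidiers
#' @export
tidy.cea_result <- function(x, ...) {
  x$incrementals
}

#' @rdname urocea-tidiers
#' @export
glance.cea_result <- function(x, ...) {
  tibble(
    analysis = x$settings$analysis, rescaled = x$settings$rescale,
    perspective = x$settings$perspective,
    n = x$fit$n, B = x$settings$B,
    label = x$icer$label, icer = x$icer$icer
  )
}

#' @rdname urocea-tidiers
#' @export
tidy.mi_cea_result <- function(x, ...) {
  x$pooled
}

#' @rdname urocea-tidiers
#' @export
tidy.markov_result <- function(x, ...) {
  x$results
}

#' @rdname urocea-tidiers
#' @export
glance.markov_result <- function(x, ...) {
  tibble(delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
         label = x$icer$label, icer = x$icer$icer)
}

#' @rdname urocea-tidiers
#' @export
tidy.psa_result <- function(x, ...) {
  x$ceac
}

#' @rdname urocea-tidiers
#' @export
tidy.uro_truth <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}
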