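#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_points tibble from [ceac()] (`lambda`, `strategy`,
#'   `probability`).
#' @return a ggplot.
#' @export
plot_ceac <- function(ceac_points) {
  ggplot2::ggplot(ceac_points,
                  ggplot2::aes(x = .data$lambda, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY (£)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cea_result <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::annotate("point", x = object$fit$delta_qaly,
                      y = object$fit$delta_cost, colour = "red", size = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (£)",
                  title = "Cost-effectiveness plane (bootstrap draws)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psa_result <- function(object, ...) {
  plot_ceac(object$ceac) +
    ggplot2::labs(title = "CEAC (Markov model, probabilistic draws)")
}

#' @export
autoplot.cohort_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trace[, c("time", "symptom_free", "symptomatic", "deceased")],
    -"time", names_to = "state", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$proportion,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years", y = "State occupancy",
                  title = paste("Cohort trace:", object$strategy)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
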