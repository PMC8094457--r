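#' Classify an incremental cost/QALY pair
#'
#' Increments are intervention (urethroplasty) minus comparator
#' (urethrotomy). The intervention is *dominated* when it costs more and
#' yields fewer QALYs, *dominant* when it costs less and yields more; when
#' both increments share a sign the ICER (incremental cost per QALY) is
#' reported. A zero QALY increment with a non-zero cost increment is resolved
#' by cost minimisation (dearer = dominated, cheaper = dominant) and flagged.
#'
#' @param delta_cost incremental cost (intervention minus comparator).
#' @param delta_qaly incremental QALYs.
#' @return one-row tibble: `label` (`"icer"`, `"dominant"` or `"dominated"`,
#'   from the intervention's viewpoint), `icer` (NA unless `label == "icer"`),
#'   `flagged` (tie rule used).
#' @export
#' @examples
#' classify_icer(2148, -0.01)  # intervention dominated
#' classify_icer(1500, 0.005)  # ICER 300000
classify_icer <- function(delta_cost, delta_qaly) {
  if (!is.finite(delta_cost) || !is.finite(delta_qaly)) {
    abort("`delta_cost` and `delta_qaly` must be finite.")
  }
  flagged <- FALSE
  if (delta_qaly == 0 && delta_cost != 0) {
    label <- if (delta_cost > 0) "dominated" else "dominant"
    flagged <- TRUE
    icer <- NA_real_
  } else if (delta_cost > 0 && delta_qaly < 0) {
    label <- "dominated"; icer <- NA_real_
  } else if (delta_cost < 0 && delta_qaly > 0) {
    label <- "dominant"; icer <- NA_real_
  } else if (delta_cost == 0 && delta_qaly == 0) {
    label <- "icer"; icer <- NA_real_; flagged <- TRUE
  } else {
    label <- "icer"; icer <- delta_cost / delta_qaly
  }
  tibble(label = label, icer = icer, flagged = flagged)
}

#' Arm-mean increments
#'
#' Convenience step used when feeding published arm-level summaries through
#' the ICER classification: increments are intervention minus comparator.
#'
#' @param intervention_value,comparator_value arm-level means (cost or QALY).
#' @return increment(s).
#' @export
increment <- function(intervention_value, comparator_value) {
  intervention_value - comparator_value
}
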