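#' Scheduled EQ-5D-5L collection points
#'
#' The trial design collects EQ-5D-5L at eleven scheduled points: baseline,
#' immediately prior to surgery, one week after catheter removal, 3, 6, 9, 12
#' and 24 months after surgery, 18 and 24 months after randomisation, and at
#' the end of study. Labels are ordered by their nominal calendar position.
#'
#' @return character vector of timepoint labels.
#' @export
eq5d_timepoints <- function() {
  c(
    "baseline", "pre_surgery", "cath_1wk",
    "m3_post_surgery", "m6_post_surgery", "m9_post_surgery",
    "m12_post_surgery", "m24_post_surgery",
    "m18_post_rand", "m24_post_rand", "end_of_study"
  )
}

# Labels that exist for participants who never had the index operation.
rand_anchored_timepoints <- function() {
  c("baseline", "m18_post_rand", "m24_post_rand", "end_of_study")
}

#' EQ-5D-5L dimension names
#'
#' @return character vector of the five dimension column names used in
#'   observation tables.
#' @export
eq5d_dimensions <- function() {
  c("mobility", "self_care", "usual_activities",
    "pain_discomfort", "anxiety_depression")
}

# Mid-range points accepted by the complete-case rules.
midrange_post_rand <- function() {
  c("m3_post_surgery", "m6_post_surgery", "m9_post_surgery",
    "m12_post_surgery", "m18_post_rand")
}

midrange_post_surgery <- function() {
  c(midrange_post_rand(), "m24_post_rand")
}
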