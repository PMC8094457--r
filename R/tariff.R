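#' EQ-5D-5L tariffs
#'
#' A tariff (value set) maps each of the 3125 EQ-5D-5L profiles to a health
#' state utility no greater than 1, with full health (profile 11111) valued at
#' exactly 1. Two representations are supported: an additive decrement table
#' (one decrement per dimension and level, level 1 decrementing zero) and a
#' complete 3125-row lookup. Published national value sets are licensed
#' separately and are therefore supplied by the user as a file; the packaged
#' [toy_tariff()] is a transparent synthetic value set used in examples and
#' tests.
#'
#' @param decrements a 5 x 5 numeric matrix, rows named by
#'   [eq5d_dimensions()], columns levels 1 to 5, giving the utility subtracted
#'   from 1 for each dimension at each level.
#' @return an object of class `eq5d_tariff`.
#' @export
eq5d_tariff <- function(decrements) {
  decrements <- as.matrix(decrements)
  if (!identical(dim(decrements), c(5L, 5L))) {
    abort("`decrements` must be a 5 x 5 matrix (dimension x level).")
  }
  rownames(decrements) <- eq5d_dimensions()
  if (any(abs(decrements[, 1]) > 1e-12)) {
    abort("Level-1 decrements must be zero so that profile 11111 scores 1.")
  }
  if (any(decrements < -1e-12)) {
    abort("Decrements must be non-negative (utilities never exceed 1).")
  }
  structure(list(type = "decrement", decrements = decrements),
            class = "eq5d_tariff")
}

#' @rdname eq5d_tariff
#' @param values named numeric vector of length 3125; names are the
#'   five-digit profile strings (e.g. `"21345"`).
#' @export
eq5d_tariff_lookup <- function(values) {
  if (length(values) != 3125 || is.null(names(values))) {
    abort("`values` must be a named numeric vector with 3125 entries.")
  }
  if (abs(values[["11111"]] - 1) > 1e-12) {
    abort("A tariff must value profile 11111 at exactly 1.")
  }
  if (any(values > 1 + 1e-12)) {
    abort("Tariff values must not exceed 1.")
  }
  structure(list(type = "lookup", values = values), class = "eq5d_tariff")
}

#' Synthetic illustrative tariff
#'
#' Each level above 1 subtracts 0.05 x (level - 1) in every dimension, so
#' utilities lie on a 0.05 grid from 1 (profile 11111) down to 0 (55555).
#' This synthetic value set stands in for licensed national tariffs in
#' examples and tests.
#'
#' @param step decrement per level step (default 0.05).
#' @return an `eq5d_tariff`.
#' @export
#' @examples
#' score_profile(c(2, 1, 1, 1, 1), toy_tariff())
toy_tariff <- function(step = 0.05) {
  dec <- outer(rep(1, 5), (0:4) * step)
  eq5d_tariff(dec)
}

#' Read a tariff from a delimited file
#'
#' Accepts either a decrement table with columns `dimension`, `level`,
#' `decrement` (25 rows) or a full lookup with columns `state` (five-digit
#' profile) and `value` (3125 rows).
#'
#' @param path file path.
#' @return an `eq5d_tariff`.
#' @export
read_tariff <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("dimension", "level", "decrement") %in% names(df))) {
    dec <- matrix(0, 5, 5, dimnames = list(eq5d_dimensions(), 1:5))
    for (i in seq_len(nrow(df))) {
      dec[df$dimension[i], df$level[i]] <- df$decrement[i]
    }
    eq5d_tariff(dec)
  } else if (all(c("state", "value") %in% names(df))) {
    eq5d_tariff_lookup(setNames(df$value, sprintf("%05d", as.integer(df$state))))
  } else {
    abort("Tariff file needs columns dimension/level/decrement or state/value.")
  }
}

#' Score EQ-5D-5L profiles
#'
#' @param profile an integer vector of five levels (mobility, self-care,
#'   usual activities, pain/discomfort, anxiety/depression) or an n x 5
#'   matrix of such rows. Any `NA` level makes the whole profile missing.
#' @param tariff an [eq5d_tariff()].
#' @return utility value(s), `NA` where the profile is incomplete.
#' @export
#' @examples
#' score_profile(c(1, 1, 1, 1, 1), toy_tariff())
score_profile <- function(profile, tariff) {
  stopifnot(inherits(tariff, "eq5d_tariff"))
  m <- if (is.matrix(profile)) profile else matrix(profile, ncol = 5)
  if (ncol(m) != 5) abort("A profile has exactly five dimension levels.")
  ok <- !is.na(m)
  if (any(m[ok] < 1 | m[ok] > 5 | m[ok] != floor(m[ok]))) {
    abort("EQ-5D-5L levels must be integers in 1..5.")
  }
  complete <- rowSums(ok) == 5L
  out <- rep(NA_real_, nrow(m))
  if (any(complete)) {
    mc <- m[complete, , drop = FALSE]
    if (tariff$type == "decrement") {
      dec <- tariff$decrements
      tot <- vapply(seq_len(nrow(mc)), function(i) {
        sum(dec[cbind(1:5, mc[i, ])])
      }, numeric(1))
      out[complete] <- 1 - tot
    } else {
      keys <- apply(mc, 1, paste0, collapse = "")
      out[complete] <- unname(tariff$values[keys])
    }
  }
  if (length(out) == 1 && !is.matrix(profile)) out[[1]] else out
}

#' Add a utility column to an observation table
#'
#' @param observations tibble with the five dimension columns of
#'   [eq5d_dimensions()].
#' @param tariff an [eq5d_tariff()].
#' @return `observations` with a `utility` column (`NA` when any level is
#'   missing).
#' @export
add_utilities <- function(observations, tariff = toy_tariff()) {
  m <- as.matrix(observations[, eq5d_dimensions()])
  observations$utility <- score_profile(m, tariff)
  observations
}
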