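#' Parameter distributions for probabilistic sensitivity analysis
#'
#' Each uncertain parameter is assigned a distribution by domain convention:
#' beta for probabilities and utilities, gamma for costs, with hyperparameters
#' matched to the parameter's mean and standard error by the method of
#' moments. A standard error of zero makes the parameter degenerate at its
#' mean.
#'
#' @param spec a [markov_spec()] supplying the means.
#' @param rel_se standard error as a fraction of the mean (applied to every
#'   parameter unless overridden).
#' @param overrides named list of per-parameter standard errors, keyed as in
#'   the returned `parameter` column.
#' @return tibble of `parameter`, `mean`, `se`, `family`.
#' @export
default_psa_spec <- function(spec, rel_se = 0.2, overrides = list()) {
  validate_markov_spec(spec)
  grab <- function(name, value, family) {
    tibble(parameter = name, mean = value,
           se = unlist(overrides[name]) %||% (rel_se * value),
           family = family)
  }
  bind_rows(
    grab("urethroplasty.procedure_cost",
         spec$procedures$urethroplasty$procedure_cost, "gamma"),
    grab("urethrotomy.procedure_cost",
         spec$procedures$urethrotomy$procedure_cost, "gamma"),
    grab("urethroplasty.p_recur", spec$procedures$urethroplasty$p_recur, "beta"),
    grab("urethrotomy.p_recur", spec$procedures$urethrotomy$p_recur, "beta"),
    grab("p_death", spec$p_death, "beta"),
    grab("u_symptom_free", spec$u_symptom_free, "beta"),
    grab("u_symptomatic", spec$u_symptomatic, "beta"),
    grab("followup_cost", spec$followup_cost, "gamma"),
    grab("p_switch", spec$p_switch, "beta")
  )
}

#' Method-of-moments beta hyperparameters
#'
#' `alpha = m (m (1 - m) / s^2 - 1)`, `beta = alpha (1 - m) / m`. The standard
#' error must satisfy `s^2 < m (1 - m)` for the moments to be feasible.
#'
#' @param mean,se distribution mean and standard error.
#' @param parameter name used in error messages.
#' @return named vector `c(shape1, shape2)`.
#' @export
#' @examples
#' beta_moments(0.2, 0.05)
beta_moments <- function(mean, se, parameter = "parameter") {
  if (mean <= 0 || mean >= 1) {
    abort(sprintf("`%s`: beta mean must lie strictly in (0, 1).", parameter))
  }
  if (se^2 >= mean * (1 - mean)) {
    abort(sprintf(
      "`%s`: standard error %.4g is too large for a beta with mean %.4g.",
      parameter, se, mean))
  }
  a <- mean * (mean * (1 - mean) / se^2 - 1)
  c(shape1 = a, shape2 = a * (1 - mean) / mean)
}

gamma_moments <- function(mean, se, parameter = "parameter") {
  if (mean <= 0) {
    abort(sprintf("`%s`: gamma mean must be positive.", parameter))
  }
  shape <- (mean / se)^2
  c(shape = shape, rate = shape / mean)
}

draw_parameter <- function(n, mean, se, family, parameter) {
  if (se == 0) return(rep(mean, n))
  switch(family,
    beta = {
      p <- beta_moments(mean, se, parameter)
      rbeta(n, p[["shape1"]], p[["shape2"]])
    },
    gamma = {
      p <- gamma_moments(mean, se, parameter)
      rgamma(n, shape = p[["shape"]], rate = p[["rate"]])
    },
    abort(sprintf("`%s`: unknown distribution family `%s`.", parameter, family))
  )
}

set_spec_parameter <- function(spec, name, value) {
  if (grepl("\\.", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    spec$procedures[[parts[1]]][[parts[2]]] <- value
  } else {
    spec[[name]] <- value
  }
  spec
}

#' Probabilistic sensitivity analysis of the Markov model
#'
#' Samples every parameter of `psa_spec` from its assigned distribution,
#' reruns both strategies per draw, and summarises the draws as a CEAC with
#' [ceac()]. Fixed seeds reproduce draws exactly; with all standard errors
#' zero every draw equals the deterministic result.
#'
#' @param spec a [markov_spec()].
#' @param psa_spec tibble from [default_psa_spec()] (or hand-built with the
#'   same columns).
#' @param n_draws number of parameter draws.
#' @param lambda willingness-to-pay grid for the CEAC.
#' @param seed optional seed.
#' @return object of class `psa_result`: `draws` (per-draw strategy costs,
#'   QALYs and increments), `ceac`, and the inputs.
#' @export
psa <- function(spec, psa_spec = default_psa_spec(spec), n_draws = 1000,
                lambda = c(0, 10000, 20000, 30000, 50000), seed = NULL) {
  validate_markov_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  samples <- matrix(NA_real_, nrow = n_draws, ncol = nrow(psa_spec),
                    dimnames = list(NULL, psa_spec$parameter))
  for (i in seq_len(nrow(psa_spec))) {
    samples[, i] <- draw_parameter(n_draws, psa_spec$mean[i], psa_spec$se[i],
                                   psa_spec$family[i], psa_spec$parameter[i])
  }
  out <- matrix(NA_real_, nrow = n_draws, ncol = 4)
  for (b in seq_len(n_draws)) {
    sp <- spec
    for (j in seq_len(ncol(samples))) {
      sp <- set_spec_parameter(sp, colnames(samples)[j], samples[b, j])
    }
    rp <- run_cohort(sp, "urethroplasty", trace = FALSE)
    ro <- run_cohort(sp, "urethrotomy", trace = FALSE)
    out[b, ] <- c(rp$cost, rp$qaly, ro$cost, ro$qaly)
  }
  draws <- tibble(
    draw = seq_len(n_draws),
    cost_urethroplasty = out[, 1], qaly_urethroplasty = out[, 2],
    cost_urethrotomy = out[, 3], qaly_urethrotomy = out[, 4],
    delta_cost = out[, 1] - out[, 3],
    delta_qaly = out[, 2] - out[, 4]
  )
  structure(
    list(draws = draws, ceac = ceac(draws, lambda), spec = spec,
         psa_spec = psa_spec, n_draws = n_draws),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws\n")
  print(tidyr::pivot_wider(x$ceac, names_from = "lambda",
                           values_from = "probability", names_prefix = "wtp_"))
  invisible(x)
}
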