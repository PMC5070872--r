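#' Tidy a fitted occupancy model
#'
#' @param x A `zib_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`
#'   (posterior mean), `std.error`, `conf.low` / `conf.high` (central 95%
#'   credible interval) and `rhat`.
#' @export
tidy.zib_fit <- function(x, ...) x$summary

#' One-row summary of a fitted occupancy model
#'
#' @param x A `zib_fit`.
#' @param ... Unused.
#' @return A tibble: model label, cells, chains, draws, posterior-mean
#'   deviance, saturated deviance, detection estimate, worst R-hat.
#' @export
glance.zib_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_cells = x$n_obs,
    chains = x$mcmc$chains,
    draws = nrow(x$draws),
    deviance = x$deviance,
    deviance_saturated = x$deviance_saturated,
    delta = x$summary$estimate[x$summary$term == "delta"],
    max_rhat = suppressWarnings(max(x$summary$rhat, na.rm = TRUE))
  )
}

#' @export
tidy.hn_fit <- function(x, ...) x$by_period

#' @export
glance.hn_fit <- function(x, ...) {
  tibble::tibble(n_sightings = x$n_sightings,
                 n_periods = length(x$periods),
                 logLik = x$loglik,
                 truncation_m = x$truncation,
                 decay_days = x$decay_days)
}

#' @export
tidy.density_reg <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.density_reg <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, n_sites = x$n_sites)
}
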