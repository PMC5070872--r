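#' Half-normal detection-function fit with a survey-period covariate
#'
#' Maximum-likelihood fit of the half-normal detection function
#' `g(x) = exp(-x^2 / (2 sigma_p^2))` to perpendicular nest-group sighting
#' distances, with the scale varying by survey period through a log link
#' (`log sigma_p = a + b_p`, first period in sort order as reference).
#' Sharing the shape across periods lets a period with few sightings borrow
#' the detection curve from a better-sampled one (the multiple-covariate
#' distance sampling idea). Densities follow the standard line-transect
#' estimator: nest-group density `D_grp = n_p / (2 L_p ESW_p)` with
#' effective strip width `ESW_p = integral of g over [0, w]`; nest density
#' multiplies by mean group size, and weaned-gorilla density divides by
#' nest production x decay time (see [nests_to_gorillas()]).
#'
#' Variance combines, on the CV scale, the between-transect variance of the
#' encounter rate, the delta-method variance of `sigma_p` from the inverse
#' observed information, and the group-size standard error; 95% confidence
#' limits are log-normal, the usual distance-sampling convention.
#'
#' @param sightings Tibble: `transect_id`, `period`, `distance_m` (>= 0),
#'   `group_size` (nests per group).
#' @param transects Tibble: `transect_id`, `period`, `length_km`; defaults
#'   to the `transects` attribute attached by [simulate_transects()].
#' @param truncation Right-truncation distance w in metres (default `Inf`,
#'   i.e. none; always echoed in the fit).
#' @param nest_production Nests built per individual per day (default 1).
#' @param decay_days Mean days a nest remains visible (default 106).
#' @return An `hn_fit` object: `by_period` tibble (period, n, L_km, sigma,
#'   esw_m, density_group, group_size_mean, density_nest, density_gorilla,
#'   cv, density_gorilla_lcl, density_gorilla_ucl), coefficient vector
#'   (`a`, then one log-scale offset per non-reference period), `loglik`,
#'   `truncation`.
#' @export
fit_halfnormal_mcds <- function(sightings, transects = attr(sightings, "transects"),
                                truncation = Inf, nest_production = 1,
                                decay_days = 106) {
  req <- c("transect_id", "period", "distance_m", "group_size")
  miss <- setdiff(req, names(sightings))
  if (length(miss) > 0)
    abort(paste0("`sightings` is missing column(s): ", paste(miss, collapse = ", ")))
  if (is.null(transects)) abort("`transects` table required (transect_id, period, length_km).")
  s <- sightings[sightings$distance_m <= truncation, ]
  if (nrow(s) < 2) abort("Need >= 2 sightings (after truncation).")
  if (all(s$distance_m == 0)) abort("All distances are zero; scale not estimable.")
  periods <- sort(unique(transects$period))
  s$period <- as.character(s$period)
  if (!all(s$period %in% periods)) abort("Sighting periods missing from `transects`.")
  P <- matrix(0, nrow(s), length(periods) - 1)
  if (length(periods) > 1)
    for (k in 2:length(periods)) P[s$period == periods[k], k - 1] <- 1

  x <- s$distance_m
  nll <- function(par) {
    sig <- exp(par[1] + if (length(par) > 1) drop(P %*% par[-1]) else 0)
    norm <- if (is.finite(truncation))
      sig * sqrt(2 * pi) * (pnorm(truncation / sig) - 0.5)
    else sig * sqrt(pi / 2)
    -sum(-x^2 / (2 * sig^2) - log(norm))
  }
  init <- c(log(sqrt(sum(x^2) / length(x))), rep(0, length(periods) - 1))
  opt <- if (length(init) == 1) {
    o <- optim(init, nll, method = "Brent", lower = init - 5, upper = init + 5,
               hessian = TRUE)
    o
  } else optim(init, nll, method = "BFGS", hessian = TRUE)
  if (!all(is.finite(opt$par))) abort("Detection-function scale did not converge.")
  vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA_real_, length(init), length(init)))

  esw_of <- function(sig) {
    if (is.finite(truncation)) sig * sqrt(2 * pi) * (pnorm(truncation / sig) - 0.5)
    else sig * sqrt(pi / 2)
  }
  ## per-period summaries
  by_period <- purrr::map(seq_along(periods), function(k) {
    p <- periods[k]
    sp <- s[s$period == p, ]
    tp <- transects[transects$period == p, ]
    L <- sum(tp$length_km)
    if (L <= 0) abort(paste0("Non-positive transect length for period ", p))
    coef_idx <- if (k == 1) 1L else c(1L, k)
    sig <- exp(sum(opt$par[coef_idx]))
    esw <- esw_of(sig)
    n_p <- nrow(sp)
    Dg <- n_p / (2 * L * esw / 1000)          # groups km^-2 (esw m -> km)
    gsz <- if (n_p > 0) mean(sp$group_size) else NA_real_
    Dn <- Dg * gsz
    Dw <- nests_to_gorillas(Dn, nest_production, decay_days)

    ## CV components
    cv2_n <- {
      cnt <- table(factor(sp$transect_id, levels = tp$transect_id))
      K <- nrow(tp)
      if (K >= 2 && n_p > 0) {
        er <- n_p / L
        v <- L * sum(tp$length_km * (as.numeric(cnt) / tp$length_km - er)^2) / (K - 1)
        v / n_p^2
      } else if (n_p > 0) 1 / n_p else NA_real_
    }
    cv2_sig <- {
      g <- numeric(length(init)); g[coef_idx] <- 1
      v <- drop(t(g) %*% vc %*% g)            # var of log sigma_p
      if (is.finite(v) && v > 0) v else 0     # CV(sigma) ~ sd(log sigma)
    }
    cv2_gs <- if (n_p > 1) var(sp$group_size) / n_p / gsz^2 else 0
    cv <- sqrt(sum(c(cv2_n, cv2_sig, cv2_gs), na.rm = TRUE))
    C <- exp(1.96 * sqrt(log(1 + cv^2)))
    tibble::tibble(period = p, n = n_p, L_km = L, sigma = sig, esw_m = esw,
                   density_group = Dg, group_size_mean = gsz,
                   density_nest = Dn, density_gorilla = Dw, cv = cv,
                   density_gorilla_lcl = Dw / C, density_gorilla_ucl = Dw * C)
  })
  structure(list(
    by_period = dplyr::bind_rows(by_period),
    coef = setNames(opt$par, c("log_sigma_ref",
                               if (length(periods) > 1) paste0("log_ratio_", periods[-1]))),
    vcov = vc, loglik = -opt$value, truncation = truncation,
    periods = periods, n_sightings = nrow(s),
    nest_production = nest_production, decay_days = decay_days
  ), class = "hn_fit")
}

#' @export
print.hn_fit <- function(x, ...) {
  cat(sprintf("<hn_fit> half-normal, %d sightings, %d period(s), truncation %s m, logLik %.2f\n",
              x$n_sightings, length(x$periods),
              ifelse(is.finite(x$truncation), format(x$truncation), "none"),
              x$loglik))
  print(x$by_period)
  invisible(x)
}

#' Convert standing nest density to weaned-gorilla density
#'
#' Each weaned individual builds `production` nests per day and a nest
#' stays visible `decay_days` days, so the standing crop of nests per
#' individual is `production * decay_days`.
#'
#' @param nest_density Nests km^-2 (>= 0).
#' @param production Nests built per individual per day (default 1).
#' @param decay_days Mean nest decay time in days (default 106).
#' @return Weaned gorilla density, km^-2.
#' @export
#' @examples
#' nests_to_gorillas(106)  # 1
nests_to_gorillas <- function(nest_density, production = 1, decay_days = 106) {
  if (decay_days <= 0) abort("`decay_days` must be > 0.")
  if (production <= 0) abort("`production` must be > 0.")
  if (any(nest_density < 0)) abort("`nest_density` must be >= 0.")
  nest_density / (production * decay_days)
}

#' Population size from density and surveyed area
#'
#' @param density Point density (km^-2).
#' @param area_km2 Site area (km^2, > 0).
#' @param density_bounds Optional `c(lower, upper)` density confidence
#'   limits, scaled the same way.
#' @param digits Rounding of the results (default 0).
#' @return A one-row tibble: `n` (+ `n_lower`, `n_upper` when bounds given).
#' @export
#' @examples
#' population_from_density(0.256, 716)  # 183
population_from_density <- function(density, area_km2, density_bounds = NULL,
                                    digits = 0) {
  if (density < 0) abort("`density` must be >= 0.")
  if (area_km2 <= 0) abort("`area_km2` must be > 0.")
  out <- tibble::tibble(n = round(density * area_km2, digits))
  if (!is.null(density_bounds)) {
    if (length(density_bounds) != 2 || density_bounds[1] > density_bounds[2])
      abort("`density_bounds` must be c(lower, upper).")
    out$n_lower <- round(density_bounds[1] * area_km2, digits)
    out$n_upper <- round(density_bounds[2] * area_km2, digits)
  }
  out
}

#' Sign encounter rate
#'
#' @param n_signs Number of signs (nests) recorded.
#' @param distance_km Distance walked, km (> 0).
#' @return Signs per km.
#' @export
encounter_rate <- function(n_signs, distance_km) {
  if (any(distance_km <= 0)) abort("`distance_km` must be > 0.")
  if (any(n_signs < 0)) abort("`n_signs` must be >= 0.")
  n_signs / distance_km
}

#' Encounter-rate trend between two surveys of one site
#'
#' Percent of the original encounter rate remaining,
#' `100 * rate_final / rate_first`, and the per-year decline,
#' `(100 - percent) / (year_final - year_first)`, both rounded to 1 dp for
#' reporting. Rates must come from the same survey method (transects with
#' transects, recces with recces).
#'
#' @param first,final Length-2 numeric `c(year, rate)`.
#' @param method_first,method_final Optional survey-method labels; a
#'   mismatch errors unless `allow_mixed_methods = TRUE`.
#' @param allow_mixed_methods Override the method check.
#' @param digits Reporting precision (default 1 dp).
#' @return A one-row tibble: `percent_of_original`, `decline_per_year`.
#' @export
#' @examples
#' trend_row(c(1994, 1.21), c(2014, 0.11))
trend_row <- function(first, final, method_first = NULL, method_final = NULL,
                      allow_mixed_methods = FALSE, digits = 1) {
  if (length(first) != 2 || length(final) != 2)
    abort("`first` and `final` must each be c(year, rate).")
  if (first[2] <= 0) abort("First encounter rate must be > 0.")
  if (final[2] < 0) abort("Final encounter rate must be >= 0.")
  if (final[1] <= first[1]) abort("Final year must be after first year.")
  if (!is.null(method_first) && !is.null(method_final) &&
      method_first != method_final && !allow_mixed_methods)
    abort("Survey methods differ between the two estimates; set `allow_mixed_methods = TRUE` to override.")
  pct <- 100 * final[2] / first[2]
  per_year <- (100 - pct) / (final[1] - first[1])
  tibble::tibble(percent_of_original = round(pct, digits),
                 decline_per_year = round(per_year, digits))
}

#' Average decline across sites
#'
#' Unweighted arithmetic means of the total decline (`100 - percent of
#' original`) and of the per-year decline over a set of sites.
#'
#' @param trends Tibble with `percent_of_original` and `decline_per_year`
#'   (and optionally `site`).
#' @param sites Optional site names to subset on (requires a `site`
#'   column); default all rows.
#' @param digits Reporting precision (default 1 dp).
#' @return A one-row tibble: `mean_total_decline`, `mean_decline_per_year`,
#'   `n_sites`.
#' @export
aggregate_decline <- function(trends, sites = NULL, digits = 1) {
  if (!is.null(sites)) {
    if (!"site" %in% names(trends)) abort("`trends` has no `site` column.")
    trends <- trends[trends$site %in% sites, ]
  }
  if (nrow(trends) == 0) abort("No sites selected.")
  tibble::tibble(
    mean_total_decline = round(mean(100 - trends$percent_of_original), digits),
    mean_decline_per_year = round(mean(trends$decline_per_year), digits),
    n_sites = nrow(trends)
  )
}

#' Combined percent reduction in numbers across site sectors
#'
#' Pools populations across sectors before and after:
#' `100 * (1 - sum(N_now) / sum(N_then))`.
#'
#' @param pop_table Tibble with `n_then` and `n_now` (one row per sector).
#' @param digits Reporting precision (default 1 dp).
#' @return Percent reduction (scalar).
#' @export
#' @examples
#' combined_site_decline(tibble::tibble(n_then = c(5635, 1188), n_now = c(655, 258)))
combined_site_decline <- function(pop_table, digits = 1) {
  req <- c("n_then", "n_now")
  miss <- setdiff(req, names(pop_table))
  if (length(miss) > 0)
    abort(paste0("`pop_table` is missing column(s): ", paste(miss, collapse = ", ")))
  if (sum(pop_table$n_then) <= 0) abort("Total `n_then` must be > 0.")
  if (any(pop_table$n_now < 0)) abort("`n_now` must be >= 0.")
  round(100 * (1 - sum(pop_table$n_now) / sum(pop_table$n_then)), digits)
}
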