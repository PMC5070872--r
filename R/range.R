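#' True Skill Statistic
#'
#' Sensitivity + specificity - 1 for a binary presence/absence prediction:
#' 1 is perfect skill, 0 no better than chance (e.g. predicting presence
#' everywhere), negative worse than chance.
#'
#' @param predicted,observed Binary (0/1 or logical) vectors of equal
#'   length; `observed` must contain both classes.
#' @return TSS in [-1, 1].
#' @export
#' @examples
#' tss(c(1, 0, 0, 0), c(1, 1, 0, 0))  # 0.5
tss <- function(predicted, observed) {
  predicted <- as.integer(as.logical(predicted))
  observed <- as.integer(as.logical(observed))
  if (length(predicted) != length(observed) || length(observed) < 1)
    abort("`predicted` and `observed` must be equal-length, non-empty.")
  if (length(unique(observed)) < 2)
    abort("`observed` must contain both presences and absences.")
  sens <- sum(predicted == 1 & observed == 1) / sum(observed == 1)
  spec <- sum(predicted == 0 & observed == 0) / sum(observed == 0)
  sens + spec - 1
}

#' Probability threshold maximizing the True Skill Statistic
#'
#' Scans a regular grid of candidate thresholds over [0, 1] and returns the
#' one maximizing the TSS of `theta > threshold` against the observations;
#' ties are broken toward the smallest threshold.
#'
#' @param theta Predicted probabilities of presence for the evaluation
#'   cells.
#' @param observed Binary observed presence for the same cells (both
#'   classes required). With effort data, detected cells are presences and
#'   sampled/forced cells without sign are absences.
#' @param step Grid step for the threshold scan (default 0.01).
#' @return A list: `threshold`, `tss` (the maximum), and the full `scan`
#'   tibble (threshold, tss).
#' @export
optimal_threshold <- function(theta, observed, step = 0.01) {
  observed <- as.integer(as.logical(observed))
  if (length(theta) != length(observed))
    abort("`theta` and `observed` must have equal length.")
  grid <- seq(0, 1, by = step)
  scores <- vapply(grid, function(t) tss(theta > t, observed), numeric(1))
  best <- which.max(scores)   # which.max returns the first (smallest) maximum
  list(threshold = grid[best], tss = scores[best],
       scan = tibble::tibble(threshold = grid, tss = scores))
}

#' Binarize a probability-of-presence map into a range map
#'
#' A cell is in the range when its probability of presence strictly exceeds
#' the threshold; the range area is the presence-cell count times the cell
#' area. Apply separately to the posterior-mean map and the 2.5% / 97.5%
#' quantile maps (re-optimizing the threshold on each) to obtain the mean
#' range and its credibility envelope.
#'
#' @param theta_map Tibble with `cell_id` and a probability column.
#' @param threshold Probability threshold in [0, 1].
#' @param cell_area_km2 Area of one cell (default 25 for a 5-km grid).
#' @param prob_col Name of the probability column (default `theta_mean`).
#' @param variant Label: `"mean"`, `"lower"` or `"upper"`.
#' @return A `range_map` tibble (`cell_id`, `presence`) with attributes
#'   `threshold`, `area_km2`, `variant`.
#' @export
derive_range <- function(theta_map, threshold, cell_area_km2 = 25,
                         prob_col = "theta_mean", variant = "mean") {
  if (threshold < 0 || threshold > 1) abort("`threshold` must lie in [0, 1].")
  if (!prob_col %in% names(theta_map))
    abort(paste0("Column `", prob_col, "` not found."))
  pres <- theta_map[[prob_col]] > threshold
  out <- tibble::tibble(cell_id = theta_map$cell_id, presence = pres)
  attr(out, "threshold") <- threshold
  attr(out, "area_km2") <- sum(pres) * cell_area_km2
  attr(out, "variant") <- variant
  class(out) <- c("range_map", class(out))
  out
}

#' @export
print.range_map <- function(x, ...) {
  cat(sprintf("<range_map> %s: %d presence cells, %.0f km2 (threshold %.2f)\n",
              attr(x, "variant"), sum(x$presence), attr(x, "area_km2"),
              attr(x, "threshold")))
  invisible(x)
}

#' Range area in km2
#' @param range A `range_map` from [derive_range()].
#' @return Area (scalar, km2).
#' @export
range_area <- function(range) attr(range, "area_km2")

#' Calibrate gorilla density against nest encounter rate
#'
#' Ordinary least-squares regression of density (weaned individuals km^-2)
#' on individual-nest encounter rate (nests km^-1) across reference sites,
#' used to predict density at sites where only encounter rates exist.
#'
#' @param sites Tibble with columns `encounter_rate` and `density`
#'   (>= 3 sites).
#' @return A `density_reg` object wrapping the `lm` fit, with
#'   `adj_r_squared`, `slope`, `intercept`.
#' @export
fit_density_regression <- function(sites) {
  req <- c("encounter_rate", "density")
  miss <- setdiff(req, names(sites))
  if (length(miss) > 0)
    abort(paste0("`sites` is missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(sites) < 3) abort("Need >= 3 sites to fit the calibration.")
  if (any(sites$encounter_rate < 0)) abort("Encounter rates must be >= 0.")
  if (var(sites$encounter_rate) == 0)
    abort("Encounter rate has zero variance across sites.")
  fit <- lm(density ~ encounter_rate, data = sites)
  structure(list(
    lm = fit,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    adj_r_squared = summary(fit)$adj.r.squared,
    n_sites = nrow(sites), data = tibble::as_tibble(sites)
  ), class = "density_reg")
}

#' @export
print.density_reg <- function(x, ...) {
  cat(sprintf("<density_reg> density = %.4f + %.4f * e-rate (%d sites, adj R2 = %.3f)\n",
              x$intercept, x$slope, x$n_sites, x$adj_r_squared))
  invisible(x)
}

#' Predict site densities (with 95% prediction intervals) from encounter rates
#'
#' @param reg A `density_reg`.
#' @param sites Tibble with `encounter_rate` (and any id columns, carried
#'   through).
#' @return `sites` with `density_pred`, `density_lwr`, `density_upr` added.
#' @export
predict_density <- function(reg, sites) {
  stopifnot(inherits(reg, "density_reg"))
  pr <- predict(reg$lm, newdata = sites, interval = "prediction", level = 0.95)
  dplyr::mutate(tibble::as_tibble(sites),
                density_pred = pr[, "fit"],
                density_lwr = pmax(0, pr[, "lwr"]),
                density_upr = pr[, "upr"])
}

#' Area-weighted mean density
#'
#' @param densities Per-site densities (km^-2).
#' @param areas Per-site areas (km^2), all > 0.
#' @return `sum(D_s A_s) / sum(A_s)`.
#' @export
#' @examples
#' weighted_mean_density(c(0.1, 0.3), c(75, 25))  # 0.15
weighted_mean_density <- function(densities, areas) {
  if (length(densities) != length(areas)) abort("Length mismatch.")
  if (any(areas <= 0)) abort("Areas must be > 0.")
  sum(densities * areas) / sum(areas)
}

#' Combine range area and density into an abundance estimate
#'
#' The point estimate multiplies the mean-map range area by the
#' area-weighted point density. Uncertainty from both sources is combined
#' conservatively by pairing the 2.5% quantiles (lower-map area x lower
#' density bound) and the 97.5% quantiles (upper-map area x upper density
#' bound), which is wider than exact propagation.
#'
#' @param area Named-free numeric: `c(lower, point, upper)` range areas in
#'   km2, or a single point area.
#' @param density `c(lower, point, upper)` densities km^-2, or a point
#'   density.
#' @param round_to Rounding of the point estimate (default nearest 100) and
#'   `round_bounds_to` of the bounds (default nearest 10).
#' @param round_bounds_to See above.
#' @return An `abundance_estimate` tibble with one row: `n`, `n_lower`,
#'   `n_upper`, `area_km2`, `density`, plus the unrounded `n_exact`.
#' @export
#' @examples
#' estimate_abundance(19700, 0.193)  # 3,800 individuals
estimate_abundance <- function(area, density, round_to = 100,
                               round_bounds_to = 10) {
  expand3 <- function(x, nm) {
    if (any(x < 0)) abort(paste0("`", nm, "` must be non-negative."))
    if (length(x) == 1) rep(x, 3)
    else if (length(x) == 3) {
      if (is.unsorted(x)) abort(paste0("`", nm, "` bounds must be ordered (lower, point, upper)."))
      x
    } else abort(paste0("`", nm, "` must have length 1 or 3."))
  }
  a <- expand3(area, "area"); d <- expand3(density, "density")
  n_exact <- a[2] * d[2]
  out <- tibble::tibble(
    n = round(n_exact / round_to) * round_to,
    n_lower = round(a[1] * d[1] / round_bounds_to) * round_bounds_to,
    n_upper = round(a[3] * d[3] / round_bounds_to) * round_bounds_to,
    n_exact = n_exact,
    area_km2 = a[2], density = d[2]
  )
  class(out) <- c("abundance_estimate", class(out))
  out
}

#' Percent loss in range area between two dates
#'
#' @param area_now,area_then Range areas (km2); `area_then` > 0.
#' @param digits Rounding (default 1 dp).
#' @return `100 (1 - area_now / area_then)`.
#' @export
#' @examples
#' range_change(9005, 12770)  # 29.5
range_change <- function(area_now, area_then, digits = 1) {
  if (area_then <= 0) abort("`area_then` must be > 0.")
  if (area_now < 0) abort("`area_now` must be >= 0.")
  round(100 * (1 - area_now / area_then), digits)
}
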