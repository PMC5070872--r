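## cell_id -> row/col lookup for plotting, preferring columns already present
cell_rc <- function(d, fit = NULL) {
  if (all(c("row", "col") %in% names(d))) return(d)
  src <- if (!is.null(fit) && all(c("row", "col") %in% names(fit$covariates)))
    fit$covariates else NULL
  if (is.null(src)) abort("Need `row`/`col` columns (or a fit whose covariates carry them) to draw a map.")
  dplyr::left_join(d, dplyr::select(src, "cell_id", "row", "col"), by = "cell_id")
}

#' Map the posterior probability of presence
#'
#' @param object A `zib_fit`.
#' @param which Which layer to draw: `"mean"`, `"q2.5"` or `"q97.5"`.
#' @param ... Unused.
#' @return A ggplot raster of the probability-of-presence surface.
#' @export
autoplot.zib_fit <- function(object, which = c("mean", "q2.5", "q97.5"), ...) {
  which <- match.arg(which)
  col_name <- c(mean = "theta_mean", q2.5 = "theta_q2.5", q97.5 = "theta_q97.5")[which]
  d <- cell_rc(object$theta_map, object)
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data[[col_name]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(theta)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("Probability of presence (%s)", which)) +
    ggplot2::theme_minimal()
}

#' Map a binarized range
#'
#' @param object A `range_map` from [derive_range()].
#' @param fit Optional `zib_fit` supplying row/col lookups.
#' @param ... Unused.
#' @return A ggplot raster of presence cells.
#' @export
autoplot.range_map <- function(object, fit = NULL, ...) {
  d <- cell_rc(tibble::as_tibble(object), fit)
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$presence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85", `TRUE` = "darkgreen"),
                               name = "presence") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("Range (%s map): %.0f km2 at threshold %.2f",
                                  attr(object, "variant"),
                                  attr(object, "area_km2"),
                                  attr(object, "threshold"))) +
    ggplot2::theme_minimal()
}

#' Plot the fitted half-normal detection function over the distance data
#'
#' @param object An `hn_fit`.
#' @param sightings The sightings tibble the model was fitted to.
#' @param ... Unused.
#' @return A ggplot with per-period distance histograms (density scale) and
#'   the fitted detection curves rescaled to integrate like the histogram.
#' @export
autoplot.hn_fit <- function(object, sightings, ...) {
  bp <- object$by_period
  w <- if (is.finite(object$truncation)) object$truncation
       else max(sightings$distance_m) * 1.05
  curves <- dplyr::bind_rows(purrr::map(seq_len(nrow(bp)), function(k) {
    xs <- seq(0, w, length.out = 200)
    tibble::tibble(period = bp$period[k], distance_m = xs,
                   density = exp(-xs^2 / (2 * bp$sigma[k]^2)) / (bp$esw_m[k]))
  }))
  ggplot2::ggplot(sightings, ggplot2::aes(.data$distance_m)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 15, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$density), colour = "firebrick") +
    ggplot2::facet_wrap(~period) +
    ggplot2::labs(x = "perpendicular distance (m)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot the density-encounter-rate calibration
#'
#' @param object A `density_reg`.
#' @param ... Unused.
#' @return A ggplot scatter of the reference sites with the fitted line and
#'   95% prediction band.
#' @export
autoplot.density_reg <- function(object, ...) {
  rng <- range(object$data$encounter_rate)
  newd <- tibble::tibble(encounter_rate = seq(rng[1], rng[2], length.out = 100))
  pr <- predict_density(object, newd)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$encounter_rate, .data$density)) +
    ggplot2::geom_ribbon(data = pr,
                         ggplot2::aes(y = .data$density_pred,
                                      ymin = .data$density_lwr,
                                      ymax = .data$density_upr),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(data = pr, ggplot2::aes(y = .data$density_pred),
                       colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("nest encounter rate (nests " * km^-1 * ")"),
                  y = expression("gorilla density (" * km^-2 * ")")) +
    ggplot2::theme_minimal()
}
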