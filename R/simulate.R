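#' Specify a synthetic landscape with known occupancy truth
#'
#' Bundles the generative parameters for a suitability surface on a regular
#' grid: standardized covariate layers, logistic suitability coefficients,
#' an optional zero-mean Gaussian spatial field with queen-neighbour
#' dependence (the generative twin of the intrinsic CAR prior used in
#' fitting), and a constant per-replicate detection probability.
#'
#' @param n_rows,n_cols Grid dimensions in cells.
#' @param cell_size Cell side (km), default 5.
#' @param covariates Named character vector mapping covariate name to a
#'   spatial pattern: `"gradient"`, `"gaussian-blob"` or `"white-noise"`.
#' @param beta_true Suitability coefficients on the logit scale, intercept
#'   first, then one per covariate (length `length(covariates) + 1`).
#' @param v_rho_true Variance of the spatial field (>= 0; 0 disables it).
#' @param delta_true Per-replicate detection probability, in (0, 1).
#' @param seed Integer seed for all randomness in [simulate_landscape()].
#' @return A `landscape_spec` list, validated.
#' @export
landscape_spec <- function(n_rows, n_cols, cell_size = 5,
                           covariates = c(elevation = "gradient",
                                          tree_cover = "gaussian-blob",
                                          dist_deforestation = "white-noise"),
                           beta_true = c(-1, 1, 1, -1),
                           v_rho_true = 1,
                           delta_true = 0.11,
                           seed = 1L) {
  if (n_rows * n_cols < 4)
    abort("`n_rows * n_cols` must be >= 4.")
  patterns <- c("gradient", "gaussian-blob", "white-noise")
  if (length(covariates) > 0) {
    if (is.null(names(covariates)) || any(names(covariates) == ""))
      abort("`covariates` must be a named vector (name -> pattern).")
    bad <- setdiff(covariates, patterns)
    if (length(bad) > 0)
      abort(paste0("Unknown covariate pattern(s): ",
                   paste(bad, collapse = ", ")))
  }
  if (length(beta_true) != length(covariates) + 1)
    abort("`beta_true` must have length `length(covariates) + 1` (intercept first).")
  if (!is.numeric(v_rho_true) || v_rho_true < 0)
    abort("`v_rho_true` must be >= 0.")
  if (!is.numeric(delta_true) || delta_true <= 0 || delta_true >= 1)
    abort("`delta_true` must lie in (0, 1).")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, covariates = covariates,
         beta_true = as.numeric(beta_true), v_rho_true = v_rho_true,
         delta_true = delta_true, seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

## one covariate layer on the raw scale; standardized by the caller
make_layer <- function(pattern, cells, grid) {
  nx <- grid$n_cols * grid$cell_size
  ny <- grid$n_rows * grid$cell_size
  switch(pattern,
    "gradient" = {
      ang <- runif(1, 0, 2 * pi)
      cells$x_km * cos(ang) + cells$y_km * sin(ang) + rnorm(nrow(cells), 0, 0.05 * (nx + ny))
    },
    "gaussian-blob" = {
      k <- 4L
      cx <- runif(k, 0, nx); cy <- runif(k, 0, ny)
      sg <- runif(k, 0.15, 0.35) * max(nx, ny)
      val <- rep(0, nrow(cells))
      for (j in seq_len(k))
        val <- val + exp(-((cells$x_km - cx[j])^2 + (cells$y_km - cy[j])^2) / (2 * sg[j]^2))
      val
    },
    "white-noise" = rnorm(nrow(cells))
  )
}

## zero-mean GMRF with improper precision (D - W)/v: sample on the
## orthogonal complement of the null space via eigendecomposition.
sample_icar_field <- function(adj, v_rho) {
  n <- length(adj$n_neighbors)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) Q[i, adj$neighbors[[i]] + 1L] <- -1
  diag(Q) <- adj$n_neighbors
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-8 * max(eg$values)
  z <- rnorm(sum(pos))
  rho <- eg$vectors[, pos, drop = FALSE] %*% (z * sqrt(v_rho / eg$values[pos]))
  drop(rho - mean(rho))
}

#' Simulate a landscape with latent occupancy truth
#'
#' Draws covariate layers per the spec's patterns, standardizes them,
#' samples the spatial field (when `v_rho_true > 0`) from the sum-to-zero
#' constrained Gaussian Markov random field with precision proportional to
#' `D - W` (queen adjacency), forms suitability
#' `logit(theta) = X beta + rho`, and draws latent occupancy
#' `z ~ Bernoulli(theta)` per cell.
#'
#' @param spec A [landscape_spec()].
#' @return An `occu_truth` tibble with one row per cell: `cell_id`, `row`,
#'   `col`, centre coordinates, standardized covariate columns, `rho`,
#'   `theta`, `z`. The grid and spec travel as attributes `grid` / `spec`.
#' @export
#' @examples
#' tr <- simulate_landscape(landscape_spec(8, 8, seed = 42))
#' mean(tr$z)
simulate_landscape <- function(spec) {
  if (!inherits(spec, "landscape_spec")) abort("`spec` must be a landscape_spec.")
  grid <- landscape_grid(spec$n_rows, spec$n_cols, spec$cell_size)
  cells <- grid_cells(grid)
  set.seed(spec$seed)
  X <- matrix(1, nrow(cells), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(spec$covariates) > 0) {
    raw <- vapply(unname(spec$covariates), make_layer, numeric(nrow(cells)),
                  cells = cells, grid = grid)
    colnames(raw) <- names(spec$covariates)
    std <- standardize_covariates(raw)
    X <- cbind(X, std$values)
    cells <- dplyr::bind_cols(cells, tibble::as_tibble(std$values))
  }
  rho <- if (spec$v_rho_true > 0) {
    sample_icar_field(build_adjacency(grid), spec$v_rho_true)
  } else rep(0, nrow(cells))
  eta <- drop(X %*% spec$beta_true) + rho
  theta <- plogis(eta)
  z <- rbinom(nrow(cells), 1L, theta)
  out <- dplyr::mutate(cells, rho = rho, theta = theta, z = z)
  attr(out, "grid") <- grid
  attr(out, "spec") <- spec
  class(out) <- c("occu_truth", class(out))
  out
}

#' Simulate cell-level survey effort and detections
#'
#' Assigns each sampled cell a number of 1-km survey replicates and draws
#' detections `y ~ Binomial(n_units, z * delta)`: sign can only be recorded
#' where the cell is truly occupied (no false positives).
#'
#' @param truth An `occu_truth` from [simulate_landscape()].
#' @param n_units Replicates per cell: a single count, a range `c(min, max)`
#'   sampled uniformly per cell, or a vector over sampled cells. All counts
#'   must lie in `[2, 50]`, the replication range seen in grid-cell patrol
#'   data.
#' @param delta Per-replicate detection probability in (0, 1); defaults to
#'   the generative value in the spec.
#' @param prop_sampled Fraction of cells that receive any effort (cells are
#'   chosen uniformly at random); remaining cells are unsampled.
#' @param seed Integer seed.
#' @return A cell-effort tibble (`cell_id`, `row`, `col`, `n_units`, `y`,
#'   `detections` list-column, `is_forced_absence = FALSE`), one row per
#'   sampled cell.
#' @export
simulate_effort <- function(truth, n_units = c(2, 50), delta = NULL,
                            prop_sampled = 1, seed = 1L) {
  stopifnot(inherits(truth, "occu_truth"))
  spec <- attr(truth, "spec")
  if (is.null(delta)) delta <- spec$delta_true
  if (delta <= 0 || delta >= 1) abort("`delta` must lie in (0, 1).")
  set.seed(seed)
  n_tot <- nrow(truth)
  keep <- sort(sample(n_tot, max(1L, round(prop_sampled * n_tot))))
  n_keep <- length(keep)
  units <- if (length(n_units) == 1) rep(n_units, n_keep)
           else if (length(n_units) == 2 && n_keep != 2)
             sample(seq(n_units[1], n_units[2]), n_keep, replace = TRUE)
           else n_units
  if (length(units) != n_keep)
    abort("`n_units` must be length 1, a range c(min, max), or one count per sampled cell.")
  if (any(units < 2 | units > 50))
    abort("Replicate counts must lie in [2, 50].")
  z <- truth$z[keep]
  det <- purrr::map2(units, z, function(n, zi) rbinom(n, 1L, zi * delta))
  tibble::tibble(
    cell_id = truth$cell_id[keep],
    row = truth$row[keep], col = truth$col[keep],
    n_units = as.integer(units),
    y = vapply(det, sum, numeric(1)),
    detections = det,
    is_forced_absence = FALSE
  )
}

#' Simulate georeferenced survey tracks over a landscape
#'
#' Generates straight polyline tracks (GPS fixes every `step_km`) crossing
#' the landscape, with gorilla-sign points dropped only in occupied cells
#' as a thinned Poisson process whose per-km intensity
#' `-log(1 - delta)` makes the probability of at least one sign per 1-km
#' unit equal to the per-replicate detection probability `delta`.
#'
#' @param truth An `occu_truth`.
#' @param n_tracks Number of tracks.
#' @param length_km Track length in km (recycled).
#' @param step_km GPS fix spacing, must be <= 0.25 km for transect-style
#'   tracks.
#' @param delta Per-km sign probability given occupancy (defaults to the
#'   generative detection probability).
#' @param axis_aligned If `TRUE`, tracks run due east from a random west-edge
#'   start (useful for exact geometric checks); otherwise direction is
#'   uniform.
#' @param seed Integer seed.
#' @return A point tibble: `track_id`, `seq`, `x_km`, `y_km`, `sign`
#'   (logical), `survey_type`. Points falling outside the landscape are
#'   clipped with a warning.
#' @export
simulate_tracks <- function(truth, n_tracks = 10, length_km = 20,
                            step_km = 0.25, delta = NULL,
                            axis_aligned = FALSE, seed = 1L) {
  stopifnot(inherits(truth, "occu_truth"))
  if (step_km > 0.25) abort("`step_km` must be <= 0.25 km.")
  spec <- attr(truth, "spec"); grid <- attr(truth, "grid")
  if (is.null(delta)) delta <- spec$delta_true
  nx <- grid$n_cols * grid$cell_size
  ny <- grid$n_rows * grid$cell_size
  lam <- -log(1 - delta)   # signs per km given occupancy
  set.seed(seed)
  length_km <- rep_len(length_km, n_tracks)
  clipped <- FALSE
  pts <- purrr::map(seq_len(n_tracks), function(tid) {
    if (axis_aligned) {
      x0 <- 0; y0 <- runif(1, 0, ny); ang <- 0
    } else {
      x0 <- runif(1, 0, nx); y0 <- runif(1, 0, ny); ang <- runif(1, 0, 2 * pi)
    }
    s <- seq(0, length_km[tid], by = step_km)
    x <- x0 + s * cos(ang); y <- y0 + s * sin(ang)
    inside <- x >= 0 & x <= nx & y >= 0 & y <= ny
    if (!all(inside)) {
      clipped <<- TRUE
      keep <- seq_len(max(1L, which.max(!inside) - 1L))  # truncate at first exit
      x <- x[keep]; y <- y[keep]; s <- s[keep]
    }
    if (length(x) < 2) return(NULL)
    cell <- point_cell(grid, pmin(x, nx - 1e-9), pmin(y, ny - 1e-9))
    occupied <- truth$z[cell + 1L] == 1L
    ## thinned Poisson: each step of length step_km carries a sign point
    ## with prob 1 - exp(-lam * step_km) when the cell is occupied
    sign <- occupied & runif(length(x)) < (1 - exp(-lam * step_km))
    sign[1] <- FALSE
    tibble::tibble(track_id = tid, seq = seq_along(x),
                   x_km = x, y_km = y, sign = sign,
                   survey_type = "transect")
  })
  if (clipped) warn("Some tracks extended beyond the landscape and were clipped.")
  dplyr::bind_rows(pts)
}

#' Simulate line-transect nest-group sightings
#'
#' Perpendicular sighting distances are drawn half-normal, `|x|` with
#' `g(x) = exp(-x^2 / (2 sigma^2))`, with the scale sigma varying by survey
#' period. Group sizes (nests per group) are drawn from a shifted Poisson.
#'
#' @param sigma_by_period Named numeric vector, metres, one scale per
#'   period label (e.g. `c("1994" = 24, "2011-2015" = 12)`); all > 0.
#' @param n_groups Named integer vector of sighting counts per period
#'   (names matching `sigma_by_period`); zero counts allowed.
#' @param mean_group_size Mean nests per group (>= 1); sizes are
#'   `1 + Poisson(mean - 1)`.
#' @param L_km Named numeric vector of total transect length per period, km.
#' @param n_transects Transects per period over which length is split evenly.
#' @param seed Integer seed.
#' @return A sightings tibble (`transect_id`, `period`, `distance_m`,
#'   `group_size`) with the per-period transect table in attribute
#'   `transects` (`transect_id`, `period`, `length_km`).
#' @export
simulate_transects <- function(sigma_by_period, n_groups, mean_group_size = 3,
                               L_km, n_transects = 10, seed = 1L) {
  if (any(sigma_by_period <= 0)) abort("All `sigma_by_period` must be > 0.")
  periods <- names(sigma_by_period)
  if (is.null(periods)) abort("`sigma_by_period` must be named by period.")
  set.seed(seed)
  n_groups <- n_groups[periods]; L_km <- L_km[periods]
  sights <- purrr::map(periods, function(p) {
    ng <- n_groups[[p]]
    if (ng == 0) return(NULL)
    tibble::tibble(
      transect_id = paste0(p, "_T", sample.int(n_transects, ng, replace = TRUE)),
      period = p,
      distance_m = abs(rnorm(ng, 0, sigma_by_period[[p]])),
      group_size = 1L + rpois(ng, mean_group_size - 1)
    )
  })
  out <- dplyr::bind_rows(sights)
  if (nrow(out) == 0)
    out <- tibble::tibble(transect_id = character(), period = character(),
                          distance_m = numeric(), group_size = integer())
  transects <- dplyr::bind_rows(purrr::map(periods, function(p)
    tibble::tibble(transect_id = paste0(p, "_T", seq_len(n_transects)),
                   period = p, length_km = L_km[[p]] / n_transects)))
  attr(out, "transects") <- transects
  out
}

#' Simulate a site table with linear density-encounter-rate coupling
#'
#' Generates per-site nest encounter rates and gorilla densities related by
#' `density = intercept + slope * rate + Normal(0, noise_sd)`, the generative
#' counterpart of the density-calibration regression, plus site areas.
#'
#' @param n_sites Number of sites (>= 3).
#' @param slope,intercept True regression coefficients (density in
#'   weaned gorillas km^-2 on nests km^-1).
#' @param noise_sd Gaussian noise sd on density.
#' @param rate_range Range of encounter rates to spread sites over.
#' @param area_range Range of site areas, km^2.
#' @param seed Integer seed.
#' @return A tibble: `site`, `area_km2`, `encounter_rate`, `density`.
#' @export
simulate_sites <- function(n_sites = 9, slope = 0.16, intercept = 0.02,
                           noise_sd = 0.01, rate_range = c(0.05, 2.5),
                           area_range = c(200, 3000), seed = 1L) {
  if (n_sites < 3) abort("`n_sites` must be >= 3.")
  set.seed(seed)
  rate <- sort(runif(n_sites, rate_range[1], rate_range[2]))
  dens <- pmax(0, intercept + slope * rate + rnorm(n_sites, 0, noise_sd))
  tibble::tibble(
    site = paste0("site_", seq_len(n_sites)),
    area_km2 = round(runif(n_sites, area_range[1], area_range[2])),
    encounter_rate = rate,
    density = dens
  )
}
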