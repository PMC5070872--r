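#' MCMC settings for the occupancy samplers
#'
#' @param chains Number of parallel chains (>= 2 for convergence checks).
#' @param iters Total iterations per chain.
#' @param burn Burn-in iterations discarded per chain.
#' @param thin Thinning interval for recorded draws.
#' @return A validated list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2, iters = 10000, burn = 5000, thin = 5) {
  if (chains < 1) abort("`chains` must be >= 1.")
  if (burn >= iters) abort("`burn` must be smaller than `iters`.")
  if (thin < 1) abort("`thin` must be >= 1.")
  structure(list(chains = as.integer(chains), iters = as.integer(iters),
                 burn = as.integer(burn), thin = as.integer(thin)),
            class = "mcmc_control")
}

#' Zero-inflated binomial occupancy log-likelihood
#'
#' The observation model behind the fits: detections `y_i ~ Binomial(n_i,
#' z_i * delta)` with latent suitability `z_i ~ Bernoulli(theta_i)`. With
#' `z` supplied the joint log-likelihood of `(y, z)` is returned; with
#' `z = NULL` the latent state is marginalized analytically, giving the
#' per-cell mixture `theta * Binom(y | n, delta)` for `y > 0` and
#' `(1 - theta) + theta (1 - delta)^n` for `y = 0`.
#'
#' @param y,n Detections and replicates per cell.
#' @param theta Per-cell suitability probabilities.
#' @param delta Detection probability.
#' @param z Optional latent occupancy vector in \{0, 1\}.
#' @return The log-likelihood (scalar).
#' @export
zib_loglik <- function(y, n, theta, delta, z = NULL) {
  stopifnot(length(y) == length(n), length(theta) == length(y))
  if (!is.null(z)) {
    sum(dbinom(y, n, z * delta, log = TRUE)) +
      sum(dbinom(z, 1, theta, log = TRUE))
  } else {
    ll <- ifelse(y > 0,
                 log(theta) + dbinom(y, n, delta, log = TRUE),
                 log((1 - theta) + theta * (1 - delta)^n))
    sum(ll)
  }
}

## shared validation + design-matrix assembly for both fits
prepare_zib_inputs <- function(effort, covariates, covariate_names) {
  req <- c("cell_id", "n_units", "y")
  miss <- setdiff(req, names(effort))
  if (length(miss) > 0)
    abort(paste0("`effort` is missing column(s): ", paste(miss, collapse = ", ")))
  if (any(effort$n_units < 1)) abort("Every included cell needs `n_units` >= 1.")
  if (any(effort$y > effort$n_units)) abort("Found y > n_units.")
  if (all(effort$y == 0)) {
    if (all(effort$is_forced_absence %||% FALSE))
      abort("All detections are zero and all cells are forced absences; the model is unidentifiable.")
    if (sum(effort$y) == 0)
      abort("No detections anywhere; suitability and detection cannot be separated.")
  }
  if (is.null(covariates)) {
    covariates <- tibble::tibble(cell_id = effort$cell_id)
    covariate_names <- character(0)
  }
  if (!"cell_id" %in% names(covariates))
    abort("`covariates` must carry a `cell_id` column.")
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(covariates),
                               c("cell_id", "row", "col", "x_km", "y_km",
                                 "rho", "theta", "z"))
  miss <- setdiff(covariate_names, names(covariates))
  if (length(miss) > 0)
    abort(paste0("Covariate(s) not found: ", paste(miss, collapse = ", ")))
  Xfull <- cbind(`(Intercept)` = 1,
                 as.matrix(covariates[, covariate_names, drop = FALSE]))
  if (any(!is.finite(Xfull))) abort("Non-finite covariate values.")
  idx <- match(effort$cell_id, covariates$cell_id)
  if (anyNA(idx)) abort("Some effort cells have no covariate row.")
  list(Xfull = Xfull, Xobs = Xfull[idx, , drop = FALSE],
       covariates = covariates, covariate_names = covariate_names)
}

run_zib_chains <- function(y, n, Xobs, cell_of_obs, spatial, ncell,
                           adj, n_comp, mcmc, prior_beta_var, vrho_max, seed) {
  p <- ncol(Xobs)
  purrr::map(seq_len(mcmc$chains), function(ch) {
    set.seed(seed + 1000L * ch)
    zib_chain_cpp(
      y = as.integer(y), n = as.integer(n), X = Xobs,
      cell_of_obs = as.integer(cell_of_obs), spatial = spatial,
      ncell = as.integer(ncell),
      adj_ids = if (spatial) adj$adj_ids else integer(0),
      adj_start = if (spatial) adj$adj_start else integer(0),
      n_comp = as.integer(n_comp),
      n_iter = mcmc$iters, n_burn = mcmc$burn, thin = mcmc$thin,
      beta_var = prior_beta_var, vrho_max = vrho_max,
      beta0 = rnorm(p, 0, 1), delta0 = runif(1, 0.05, 0.95),
      vrho0 = runif(1, 0.5, 5))
  })
}

## assemble the fitted-object bookkeeping shared by fit_zib / fit_zib_icar
finish_zib_fit <- function(chains_out, prep, effort, spatial, adj, mcmc,
                           prior_beta_var, vrho_max, call_name) {
  p <- ncol(prep$Xobs)
  terms <- c(colnames(prep$Xobs), "delta", if (spatial) "V_rho")
  chain_mats <- purrr::map(chains_out, function(cc) {
    m <- cbind(cc$beta, cc$delta, if (spatial) cc$vrho)
    colnames(m) <- terms
    m
  })
  draws <- do.call(rbind, chain_mats)
  rhat <- if (length(chain_mats) < 2) rep(NA_real_, length(terms)) else
    vapply(seq_along(terms), function(j) {
      suppressWarnings(gelman_rubin(
        vapply(chain_mats, function(m) m[, j], numeric(nrow(chain_mats[[1]])))))
    }, numeric(1))
  summary <- tibble::tibble(
    term = terms,
    estimate = colMeans(draws),
    std.error = apply(draws, 2, sd),
    conf.low = apply(draws, 2, quantile, 0.025),
    conf.high = apply(draws, 2, quantile, 0.975),
    rhat = rhat
  )
  if (any(is.finite(rhat) & rhat > 1.1))
    warn(paste0("Convergence flag: R-hat > 1.1 for ",
                paste(terms[is.finite(rhat) & rhat > 1.1], collapse = ", ")))

  beta_draws <- draws[, seq_len(p), drop = FALSE]
  delta_draws <- draws[, "delta"]
  rho_draws <- if (spatial) do.call(rbind, purrr::map(chains_out, "rho")) else NULL

  ## posterior probability-of-presence map over the supplied covariate grid
  eta <- prep$Xfull %*% t(beta_draws)
  if (spatial) {
    cell_idx <- prep$covariates$cell_id + 1L
    eta <- eta + t(rho_draws[, cell_idx, drop = FALSE])
  }
  th <- plogis(eta)
  theta_map <- tibble::tibble(
    cell_id = prep$covariates$cell_id,
    theta_mean = rowMeans(th),
    theta_q2.5 = apply(th, 1, quantile, 0.025),
    theta_q97.5 = apply(th, 1, quantile, 0.975)
  )

  dev_draws <- unlist(purrr::map(chains_out, "deviance"))
  phat <- effort$y / effort$n_units
  dev_sat <- sum(-2 * dbinom(effort$y, effort$n_units, phat, log = TRUE))

  structure(list(
    summary = summary, draws = draws, chain_draws = chain_mats,
    rho_draws = rho_draws,
    theta_map = theta_map,
    deviance = mean(dev_draws), deviance_draws = dev_draws,
    deviance_saturated = dev_sat,
    spatial = spatial, adjacency = if (spatial) adj,
    effort = effort, covariate_names = prep$covariate_names,
    covariates = prep$covariates,
    mcmc = mcmc, prior_beta_var = prior_beta_var, vrho_max = vrho_max,
    n_obs = nrow(effort), model = call_name
  ), class = "zib_fit")
}

#' Fit the zero-inflated binomial occupancy model (no spatial effect)
#'
#' Hierarchical Bayesian fit of `y_i ~ Binomial(n_i, z_i delta)`,
#' `z_i ~ Bernoulli(theta_i)`, `logit(theta_i) = x_i' beta`, assuming
#' constant detectability across replicates and cells. Coefficients carry
#' vague `Normal(0, prior_beta_var)` priors and `delta` a uniform prior.
#' Two (or more) MCMC chains are run from overdispersed starts; convergence
#' is summarised by the Gelman-Rubin statistic per parameter, with a warning
#' above 1.1.
#'
#' @param effort Cell-effort tibble (`cell_id`, `n_units`, `y`, ...), e.g.
#'   from [build_cell_effort()] or [simulate_effort()].
#' @param covariates Tibble with `cell_id` plus standardized covariate
#'   columns, covering at least every effort cell; the probability-of-
#'   presence map is computed for every row supplied (pass the full
#'   landscape grid to map range-wide suitability).
#' @param covariate_names Covariate columns to use (default: all columns
#'   other than the coordinate/bookkeeping ones).
#' @param prior_beta_var Prior variance of each coefficient (default 1e6).
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed (each chain derives its own stream).
#' @return A `zib_fit` object; see [tidy.zib_fit()], [glance.zib_fit()],
#'   [predict_theta()].
#' @export
fit_zib <- function(effort, covariates = NULL, covariate_names = NULL,
                    prior_beta_var = 1e6, mcmc = mcmc_control(), seed = 1L) {
  prep <- prepare_zib_inputs(effort, covariates, covariate_names)
  out <- run_zib_chains(effort$y, effort$n_units, prep$Xobs,
                        cell_of_obs = rep(0L, nrow(effort)),
                        spatial = FALSE, ncell = 0L, adj = NULL, n_comp = 1L,
                        mcmc = mcmc, prior_beta_var = prior_beta_var,
                        vrho_max = 10, seed = seed)
  finish_zib_fit(out, prep, effort, spatial = FALSE, adj = NULL, mcmc = mcmc,
                 prior_beta_var = prior_beta_var, vrho_max = 10, "ZIB")
}

#' Fit the spatial (intrinsic CAR) zero-inflated binomial occupancy model
#'
#' As [fit_zib()], with an intrinsic conditional autoregressive random
#' effect `rho` added to the logit suitability: each cell's effect is
#' conditionally normal around the mean of its queen neighbours with
#' variance `V_rho / |N(i)|`, `V_rho ~ Uniform(0, vrho_max)`, and the field
#' is sum-to-zero constrained. `rho` is sampled for every landscape cell, so
#' unsampled cells borrow strength from sampled neighbours and the
#' probability-of-presence map includes the spatial effect everywhere.
#'
#' @inheritParams fit_zib
#' @param grid The [landscape_grid()] the cell ids index.
#' @param adjacency Optional precomputed [build_adjacency()] for `grid`.
#' @param vrho_max Upper bound of the uniform prior on `V_rho` (default 10).
#' @return A `zib_fit` with additional `V_rho` and `rho` posteriors.
#' @export
fit_zib_icar <- function(effort, covariates, grid, adjacency = NULL,
                         covariate_names = NULL, prior_beta_var = 1e6,
                         vrho_max = 10, mcmc = mcmc_control(), seed = 1L) {
  stopifnot(inherits(grid, "occu_grid"))
  prep <- prepare_zib_inputs(effort, covariates, covariate_names)
  if (is.null(adjacency)) adjacency <- build_adjacency(grid)
  if (length(adjacency$n_neighbors) != n_cells(grid))
    abort("`adjacency` does not match `grid`.")
  if (any(effort$cell_id >= n_cells(grid)))
    abort("Effort cell ids exceed the grid.")
  comp <- grid_components(adjacency)
  if (comp > 1)
    warn(sprintf("Grid has %d disconnected components; sum-to-zero applies overall.", comp))
  out <- run_zib_chains(effort$y, effort$n_units, prep$Xobs,
                        cell_of_obs = effort$cell_id,
                        spatial = TRUE, ncell = n_cells(grid),
                        adj = adjacency, n_comp = comp,
                        mcmc = mcmc, prior_beta_var = prior_beta_var,
                        vrho_max = vrho_max, seed = seed)
  finish_zib_fit(out, prep, effort, spatial = TRUE, adj = adjacency,
                 mcmc = mcmc, prior_beta_var = prior_beta_var,
                 vrho_max = vrho_max, "ZIB.iCAR")
}

## number of connected components of the adjacency graph
grid_components <- function(adj) {
  n <- length(adj$n_neighbors)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- adj$neighbors[[v]] + 1L
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  cur
}

#' @export
print.zib_fit <- function(x, ...) {
  cat(sprintf("<zib_fit> %s: %d cells, %d chains x %d draws, deviance %.1f\n",
              x$model, x$n_obs, x$mcmc$chains,
              nrow(x$chain_draws[[1]]), x$deviance))
  print(x$summary)
  invisible(x)
}

#' Posterior probability-of-presence map
#'
#' Per-cell posterior mean and central 95% interval of the probability of
#' presence. With `covariates = NULL` the map computed at fit time (over the
#' covariate grid supplied to the fit) is returned; otherwise the map is
#' recomputed for the new grid. New covariates must be on the same
#' (standardized) scale as the training covariates. For spatial fits the
#' per-cell `rho` posterior is included, so `covariates$cell_id` must index
#' the fitted grid.
#'
#' @param fit A `zib_fit`.
#' @param covariates Optional tibble (`cell_id` + covariate columns).
#' @return A tibble: `cell_id`, `theta_mean`, `theta_q2.5`, `theta_q97.5`.
#' @export
predict_theta <- function(fit, covariates = NULL) {
  stopifnot(inherits(fit, "zib_fit"))
  if (is.null(covariates)) return(fit$theta_map)
  miss <- setdiff(fit$covariate_names, names(covariates))
  if (length(miss) > 0)
    abort(paste0("Covariate(s) missing: ", paste(miss, collapse = ", ")))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(covariates[, fit$covariate_names, drop = FALSE]))
  if (any(!is.finite(X))) abort("Non-finite covariate values.")
  p <- length(fit$covariate_names) + 1
  eta <- X %*% t(fit$draws[, seq_len(p), drop = FALSE])
  if (fit$spatial) {
    if (!"cell_id" %in% names(covariates))
      abort("Spatial prediction needs `cell_id` in `covariates`.")
    eta <- eta + t(fit$rho_draws[, covariates$cell_id + 1L, drop = FALSE])
  }
  th <- plogis(eta)
  tibble::tibble(
    cell_id = covariates$cell_id %||% seq_len(nrow(covariates)) - 1L,
    theta_mean = rowMeans(th),
    theta_q2.5 = apply(th, 1, quantile, 0.025),
    theta_q97.5 = apply(th, 1, quantile, 0.975)
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between-chain and within-chain variance for one scalar
#' parameter; values near 1 indicate the chains have mixed.
#'
#' @param chains A matrix with one column per chain (iterations in rows), or
#'   a list of equal-length numeric vectors. At least 2 chains of >= 10
#'   draws.
#' @return The R-hat statistic (scalar); `NA` with a warning when all chains
#'   are constant (the diagnostic is undefined).
#' @export
#' @examples
#' gelman_rubin(cbind(rnorm(1000), rnorm(1000)))
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) abort("Need at least 2 chains.")
  if (n < 10) abort("Need at least 10 draws per chain.")
  W <- mean(apply(chains, 2, var))
  B_over_n <- var(colMeans(chains))
  if (W == 0) {
    if (B_over_n == 0) { warn("All chains constant; R-hat undefined."); return(NA_real_) }
    return(Inf)
  }
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

#' Percentage of deviance explained
#'
#' `100 (D_null - D_model) / (D_null - D_full)`, where the full (saturated)
#' reference has as many parameters as observations. Orders models between
#' the null (0%) and saturated (100%) benchmarks.
#'
#' @param d_null,d_model,d_full Posterior-mean deviances of the null model,
#'   the model of interest, and the saturated model.
#' @param digits Rounding for reporting (default 0, i.e. whole percent);
#'   `NULL` to skip rounding.
#' @return Percentage (scalar).
#' @export
#' @examples
#' deviance_explained(1126.6, 798.8, 541.3)  # 56
deviance_explained <- function(d_null, d_model, d_full, digits = 0) {
  if (d_null == d_full) abort("Degenerate: d_null equals d_full.")
  if (!(d_full <= d_model && d_model <= d_null))
    warn("Deviance ordering d_full <= d_model <= d_null violated (MCMC noise?).")
  out <- 100 * (d_null - d_model) / (d_null - d_full)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
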