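# Shared fixtures: a small spatially structured world and fast MCMC settings.

quick_mcmc <- function(iters = 3000, burn = 1500, thin = 3, chains = 2) {
  mcmc_control(chains = chains, iters = iters, burn = burn, thin = thin)
}

# landscape with two informative covariates, moderate spatial field
make_world <- function(n_rows = 20, n_cols = 20, v_rho = 1, delta = 0.3,
                       beta = c(-0.5, 1, 1), seed = 7) {
  simulate_landscape(landscape_spec(
    n_rows, n_cols,
    covariates = c(elev = "gradient", tc = "gaussian-blob"),
    beta_true = beta, v_rho_true = v_rho, delta_true = delta, seed = seed))
}

truth_covariates <- function(truth) {
  nm <- names(attr(truth, "spec")$covariates)
  truth[, c("cell_id", "row", "col", nm)]
}

# brute-force marginal ZIB log-likelihood by enumerating all latent z
enumerate_zib_loglik <- function(y, n, theta, delta) {
  m <- length(y)
  total <- 0
  for (i in seq_len(m)) {
    p_i <- 0
    for (zi in 0:1)
      p_i <- p_i + dbinom(y[i], n[i], zi * delta) * dbinom(zi, 1, theta[i])
    total <- total + log(p_i)
  }
  total
}
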