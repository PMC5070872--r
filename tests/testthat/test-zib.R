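test_that("marginal and conditional ZIB log-likelihoods match brute force on a toy table", {
  y <- c(0, 2, 0, 5, 1, 0)
  n <- c(4, 6, 2, 8, 3, 5)
  theta <- c(0.2, 0.7, 0.5, 0.9, 0.4, 0.1)
  delta <- 0.3
  # marginal: analytic mixture vs enumeration over all latent z
  expect_equal(zib_loglik(y, n, theta, delta),
               enumerate_zib_loglik(y, n, theta, delta), tolerance = 1e-10)
  # conditional: directly coded Binomial + Bernoulli sum
  z <- c(0, 1, 1, 1, 1, 0)
  direct <- sum(dbinom(y, n, z * delta, log = TRUE)) +
    sum(z * log(theta) + (1 - z) * log(1 - theta))
  expect_equal(zib_loglik(y, n, theta, delta, z), direct, tolerance = 1e-10)
})

test_that("the sampler's recorded deviance equals the R marginal likelihood at its own draws", {
  tr <- make_world(10, 10, v_rho = 0, seed = 2)
  eff <- simulate_effort(tr, n_units = 8, delta = 0.3, seed = 3)
  fit <- fit_zib(eff, truth_covariates(tr), mcmc = quick_mcmc(1000, 500, 2), seed = 4)
  X <- cbind(1, as.matrix(truth_covariates(tr)[match(eff$cell_id,
             truth_covariates(tr)$cell_id), c("elev", "tc")]))
  p <- 3
  dev_r <- vapply(seq_len(nrow(fit$draws)), function(k) {
    theta <- plogis(drop(X %*% fit$draws[k, 1:p]))
    -2 * zib_loglik(eff$y, eff$n_units, theta, fit$draws[k, "delta"])
  }, numeric(1))
  expect_equal(mean(dev_r), fit$deviance, tolerance = 1e-8)
})

test_that("MCMC matches a dense grid posterior on an intercept-only problem", {
  # enough replicates per cell that occupancy and detection separate cleanly
  # (with few, weak data the vague prior leaves a theta ~ 1 plateau that
  # dominates the posterior and no estimator summarises it usefully)
  set.seed(10)
  m <- 200; n_units <- 8; theta_true <- 0.5; delta_true <- 0.5
  z <- rbinom(m, 1, theta_true)
  y <- rbinom(m, n_units, z * delta_true)
  eff <- tibble::tibble(cell_id = seq_len(m) - 1L, n_units = n_units, y = y)
  # grid posterior over (beta0, delta), same priors as the model
  b_grid <- seq(-3, 3, length.out = 241)
  d_grid <- seq(0.005, 0.995, length.out = 199)
  lp <- outer(b_grid, d_grid, Vectorize(function(b, d)
    zib_loglik(y, rep(n_units, m), rep(plogis(b), m), d) + dnorm(b, 0, 1000, log = TRUE)))
  post <- exp(lp - max(lp)); post <- post / sum(post)
  b_mean_grid <- sum(rowSums(post) * b_grid)
  d_mean_grid <- sum(colSums(post) * d_grid)
  fit <- fit_zib(eff, mcmc = quick_mcmc(6000, 2000, 2), seed = 5)
  expect_lt(abs(fit$summary$estimate[1] - b_mean_grid), 0.06)
  expect_lt(abs(fit$summary$estimate[fit$summary$term == "delta"] - d_mean_grid), 0.02)
})

test_that("detection is recovered in the easy and the 11% regimes", {
  # delta near 1, many replicates: posterior concentrates high
  tr1 <- make_world(10, 10, v_rho = 0, seed = 6)
  eff1 <- simulate_effort(tr1, n_units = 20, delta = 0.98, seed = 7)
  f1 <- fit_zib(eff1, truth_covariates(tr1), mcmc = quick_mcmc(), seed = 8)
  expect_gt(f1$summary$estimate[f1$summary$term == "delta"], 0.9)

  # the sparse-sign regime: delta = 0.11, 1,000 cells, 10 units per cell
  tr2 <- simulate_landscape(landscape_spec(
    25, 40, covariates = c(elev = "gradient", tc = "gaussian-blob"),
    beta_true = c(0, 1, 1), v_rho_true = 0, delta_true = 0.11, seed = 9))
  eff2 <- simulate_effort(tr2, n_units = 10, delta = 0.11, seed = 10)
  f2 <- fit_zib(eff2, truth_covariates(tr2), mcmc = quick_mcmc(), seed = 11)
  expect_lt(abs(f2$summary$estimate[f2$summary$term == "delta"] - 0.11), 0.05)
})

test_that("a null spatial field yields a small posterior V_rho", {
  tr <- simulate_landscape(landscape_spec(
    25, 40, covariates = c(elev = "gradient", tc = "gaussian-blob"),
    beta_true = c(0, 1, 1), v_rho_true = 0, delta_true = 0.4, seed = 12))
  eff <- simulate_effort(tr, n_units = 10, delta = 0.4, seed = 13)
  # V_rho sits against its lower boundary here, which trips the R-hat flag
  fit <- suppressWarnings(fit_zib_icar(eff, truth_covariates(tr),
                                       attr(tr, "grid"),
                                       mcmc = quick_mcmc(), seed = 14))
  vr <- fit$draws[, "V_rho"]
  expect_lt(median(vr), 0.5)
})

test_that("spatial structure is absorbed by the iCAR term", {
  # strong field, weak covariates, 1,000 cells
  tr <- simulate_landscape(landscape_spec(
    25, 40, covariates = c(elev = "gradient"), beta_true = c(0, 0.2),
    v_rho_true = 3, delta_true = 0.4, seed = 15))
  eff <- simulate_effort(tr, n_units = 10, delta = 0.4, seed = 16)
  f_flat <- fit_zib(eff, truth_covariates(tr), mcmc = quick_mcmc(), seed = 17)
  f_icar <- fit_zib_icar(eff, truth_covariates(tr), attr(tr, "grid"),
                         mcmc = quick_mcmc(8000, 4000, 4), seed = 17)
  expect_lt(f_icar$deviance, f_flat$deviance)
  # sum-to-zero constraint on the posterior-mean field
  expect_lt(abs(sum(colMeans(f_icar$rho_draws))), 1e-6 * 1000)
  # probability maps are proper and ordered
  tm <- f_icar$theta_map
  expect_true(all(tm$theta_q2.5 <= tm$theta_q97.5))
  expect_true(all(tm$theta_mean >= 0 & tm$theta_mean <= 1))
  # 95% interval calibration against the generative truth
  covered <- mean(tr$theta >= tm$theta_q2.5 & tr$theta <= tm$theta_q97.5)
  expect_gte(covered, 0.90)
  expect_lte(covered, 0.995)
})

test_that("with no covariates all cells share the same suitability", {
  tr <- make_world(10, 10, v_rho = 0, beta = c(0.3, 0, 0), seed = 18)
  eff <- simulate_effort(tr, n_units = 10, delta = 0.5, seed = 19)
  fit <- fit_zib(eff, mcmc = quick_mcmc(), seed = 20)
  expect_lt(diff(range(fit$theta_map$theta_mean)), 1e-12)
})

test_that("coefficient error shrinks with landscape size", {
  rmse_at <- function(n_rows, n_cols, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- simulate_landscape(landscape_spec(
        n_rows, n_cols, covariates = c(elev = "gradient", tc = "gaussian-blob"),
        beta_true = c(-0.5, 1, 1), v_rho_true = 0, delta_true = 0.4, seed = s))
      eff <- simulate_effort(tr, n_units = 8, delta = 0.4, seed = s + 1)
      fit <- fit_zib(eff, truth_covariates(tr), mcmc = quick_mcmc(2000, 1000, 2),
                     seed = s + 2)
      sqrt(mean((fit$summary$estimate[1:3] - c(-0.5, 1, 1))^2))
    }, numeric(1)))
  }
  expect_lt(rmse_at(40, 50, c(31, 32, 33)), rmse_at(20, 25, c(31, 32, 33)))
})

test_that("the Gelman-Rubin diagnostic behaves at its reference points", {
  set.seed(21)
  same <- cbind(rnorm(10000), rnorm(10000))
  expect_gt(gelman_rubin(same), 0.99)
  expect_lt(gelman_rubin(same), 1.02)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 100))
  expect_gt(gelman_rubin(apart), 10)
  expect_warning(r <- gelman_rubin(cbind(rep(1, 50), rep(1, 50))), "undefined")
  expect_true(is.na(r))
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(gelman_rubin(cbind(rnorm(5), rnorm(5))), "10 draws")
})

test_that("deviance-explained spans the null and saturated anchors", {
  expect_equal(deviance_explained(1000, 1000, 400), 0)
  expect_equal(deviance_explained(1000, 400, 400), 100)
  expect_error(deviance_explained(500, 500, 500), "Degenerate")
  expect_warning(deviance_explained(500, 700, 400), "ordering")
})

test_that("fit input validation catches unusable tables", {
  tr <- make_world(6, 6, seed = 22)
  eff <- simulate_effort(tr, n_units = 5, delta = 0.4, seed = 23)
  cv <- truth_covariates(tr)
  bad <- cv; bad$elev[3] <- NA
  expect_error(fit_zib(eff, bad), "Non-finite")
  none <- eff; none$y <- 0
  expect_error(fit_zib(none, cv), "No detections")
  forced <- none; forced$is_forced_absence <- TRUE
  expect_error(fit_zib(forced, cv), "unidentifiable")
})

test_that("predict_theta reuses the fitted posterior consistently", {
  tr <- make_world(8, 8, v_rho = 0, seed = 24)
  eff <- simulate_effort(tr, n_units = 8, delta = 0.4, seed = 25)
  fit <- fit_zib(eff, truth_covariates(tr), mcmc = quick_mcmc(1000, 500, 2), seed = 26)
  again <- predict_theta(fit, truth_covariates(tr))
  expect_equal(again$theta_mean, fit$theta_map$theta_mean, tolerance = 1e-12)
  expect_error(predict_theta(fit, tr[, c("cell_id", "elev")]), "missing")
})
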