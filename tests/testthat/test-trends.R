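test_that("half-normal MLE matches the closed form on untruncated data", {
  s <- simulate_transects(c(p1 = 15), n_groups = c(p1 = 400),
                          L_km = c(p1 = 120), seed = 2)
  fit <- fit_halfnormal_mcds(s)
  closed <- sqrt(sum(s$distance_m^2) / nrow(s))
  expect_equal(fit$by_period$sigma, closed, tolerance = 1e-6)
  # ESW closed form sigma * sqrt(pi/2) vs numerical integral
  sig <- fit$by_period$sigma
  expect_equal(fit$by_period$esw_m, sig * sqrt(pi / 2), tolerance = 1e-8)
  num <- integrate(function(x) exp(-x^2 / (2 * sig^2)), 0, Inf)$value
  expect_equal(fit$by_period$esw_m, num, tolerance = 1e-8)
})

test_that("the scale is recovered within sampling error at n = 500", {
  s <- simulate_transects(c(p1 = 12), n_groups = c(p1 = 500),
                          L_km = c(p1 = 150), seed = 5)
  fit <- fit_halfnormal_mcds(s)
  se <- 12 / sqrt(2 * 500)   # Fisher information of the half-normal scale
  expect_lt(abs(fit$by_period$sigma - 12), 3 * se)
})

test_that("the period covariate recovers a doubled scale on the log link", {
  s <- simulate_transects(c(old = 24, new = 12),
                          n_groups = c(old = 400, new = 400),
                          L_km = c(old = 300, new = 280), seed = 6)
  fit <- fit_halfnormal_mcds(s)
  b_hat <- fit$coef["log_ratio_old"]
  se_b <- sqrt(fit$vcov[2, 2])
  expect_lt(abs(abs(b_hat) - log(2)), 2 * se_b)
  # per-period scales track the generator's ordering
  bp <- fit$by_period
  expect_gt(bp$sigma[bp$period == "old"], bp$sigma[bp$period == "new"])
})

test_that("truncation changes the effective strip width consistently", {
  s <- simulate_transects(c(p1 = 20), n_groups = c(p1 = 600),
                          L_km = c(p1 = 200), seed = 7)
  fit <- fit_halfnormal_mcds(s, truncation = 40)
  sig <- fit$by_period$sigma
  num <- integrate(function(x) exp(-x^2 / (2 * sig^2)), 0, 40)$value
  expect_equal(fit$by_period$esw_m, num, tolerance = 1e-6)
  expect_lte(fit$by_period$esw_m, 40)
})

test_that("density is invariant to splitting a transect into two", {
  s <- simulate_transects(c(p1 = 15), n_groups = c(p1 = 200),
                          L_km = c(p1 = 100), n_transects = 1, seed = 8)
  tr1 <- attr(s, "transects")
  fit1 <- fit_halfnormal_mcds(s, transects = tr1)
  # split the single transect into two of half length, reassigning sightings
  tr2 <- tibble::tibble(transect_id = c("p1_T1", "p1_T1b"), period = "p1",
                        length_km = c(50, 50))
  s2 <- s
  s2$transect_id[seq_len(nrow(s2)) %% 2 == 0] <- "p1_T1b"
  fit2 <- fit_halfnormal_mcds(s2, transects = tr2)
  expect_equal(fit2$by_period$density_gorilla, fit1$by_period$density_gorilla,
               tolerance = 1e-10)
})

test_that("nest-to-gorilla conversion is the standing-crop identity", {
  expect_equal(nests_to_gorillas(106), 1)
  expect_equal(nests_to_gorillas(21.2), 0.2)
  expect_equal(nests_to_gorillas(42.4), 2 * nests_to_gorillas(21.2))
  expect_error(nests_to_gorillas(10, decay_days = 0), "decay_days")
  expect_error(nests_to_gorillas(-1), ">= 0")
})

test_that("site populations are density times area", {
  expect_equal(population_from_density(0.256, 716)$n, 183)
  expect_equal(population_from_density(0.122, 200)$n, 24)
  expect_equal(population_from_density(0, 500)$n, 0)
  with_ci <- population_from_density(0.256, 716, density_bounds = c(0.084, 0.749))
  expect_equal(with_ci$n_lower, 60)
  expect_equal(with_ci$n_upper, 536)
  expect_error(population_from_density(0.2, 0), "> 0")
})

test_that("encounter rates are signs per km and cross-check the generator", {
  expect_equal(encounter_rate(11, 100), 0.11)
  expect_equal(encounter_rate(0, 50), 0)
  expect_error(encounter_rate(3, 0), "> 0")
  # generator cross-check: sign points per km near the thinned-Poisson rate
  tr <- simulate_landscape(landscape_spec(
    8, 8, covariates = character(0), beta_true = 20, v_rho_true = 0,
    delta_true = 0.3, seed = 11))  # occupied everywhere
  pts <- simulate_tracks(tr, n_tracks = 60, length_km = 30, step_km = 0.25,
                         axis_aligned = TRUE, seed = 12)
  total_km <- sum(vapply(split(pts, pts$track_id), function(tk)
    sum(sqrt(diff(tk$x_km)^2 + diff(tk$y_km)^2)), numeric(1)))
  rate <- encounter_rate(sum(pts$sign), total_km)
  lambda <- -log(1 - 0.3)
  expect_lt(abs(rate - lambda), 3 * sqrt(lambda / total_km))
})

test_that("trend rows reproduce the printed arithmetic", {
  nzovu <- trend_row(c(1994, 1.21), c(2014, 0.11))
  expect_equal(nzovu$percent_of_original, 9.1)
  rgpu <- trend_row(c(1995, 0.93), c(2014, 0.17))
  expect_equal(rgpu$percent_of_original, 18.3)
  expect_equal(rgpu$decline_per_year, 4.3)
  flat <- trend_row(c(2000, 0.8), c(2010, 0.8))
  expect_equal(flat$percent_of_original, 100)
  expect_equal(flat$decline_per_year, 0)
  expect_error(trend_row(c(2014, 1), c(1994, 2)), "after")
  expect_error(trend_row(c(1994, 0), c(2014, 1)), "> 0")
  expect_error(trend_row(c(1994, 1), c(2014, 0.5),
                         method_first = "transect", method_final = "recce"),
               "methods differ")
  ok <- trend_row(c(1994, 1), c(2014, 0.5), method_first = "transect",
                  method_final = "recce", allow_mixed_methods = TRUE)
  expect_equal(ok$percent_of_original, 50)
})

test_that("aggregate decline averages the selected sites", {
  trends <- tibble::tibble(
    site = c("Balala", "Itombwe", "Nzovu", "Itebero", "Maiko", "RGPUn", "Stable"),
    percent_of_original = c(0.0, 3.3, 9.1, 3.8, 0.5, 18.3, 94.7),
    decline_per_year = c(5.6, 5.4, 4.5, 5.1, 11.1, 4.3, 2.6))
  six <- aggregate_decline(trends, sites = setdiff(trends$site, "Stable"))
  expect_equal(six$mean_total_decline, 94.2)
  expect_equal(six$n_sites, 6)
  one <- aggregate_decline(trends, sites = "Maiko")
  expect_equal(one$mean_total_decline, 99.5)
  expect_equal(one$mean_decline_per_year, 11.1)
  # permutation invariance
  shuf <- trends[sample(nrow(trends)), ]
  expect_equal(aggregate_decline(shuf), aggregate_decline(trends))
  expect_error(aggregate_decline(trends, sites = "nowhere"), "No sites")
})

test_that("pooled sector decline matches the combined arithmetic", {
  kbnp <- tibble::tibble(n_then = c(5635, 1188), n_now = c(655, 258))
  expect_equal(combined_site_decline(kbnp), 86.6)
  expect_equal(combined_site_decline(tibble::tibble(n_then = 10, n_now = 10)), 0)
  expect_equal(combined_site_decline(tibble::tibble(n_then = 10, n_now = 0)), 100)
})
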