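# occuRange

Occupancy-based range and abundance estimation for elusive species from
opportunistic sign surveys.

Rigorous population assessment is often impossible for species living in
insecure or inaccessible regions: systematic designs fail, and the usable
data are ranger-patrol tracks, reconnaissance walks and a handful of line
transects, recording indirect sign (for great apes, night nests) rather
than animals. occuRange implements a complete pipeline for this setting,
built around the workflow used to assess Grauer's-gorilla-style declines:

1. **Track processing** — georeferenced survey points are linked into
   tracks, cut at 5-km grid-cell boundaries, and divided into 1-km
   replicate units scoring presence/absence of sign
   (`build_cell_effort()`, `add_forced_absences()`).
2. **Hierarchical Bayesian occupancy** — a zero-inflated binomial mixture
   separates habitat suitability from imperfect detection,

   y_i ~ Binomial(n_i, z_i δ),  z_i ~ Bernoulli(θ_i),
   logit(θ_i) = x_iᵀβ (+ ρ_i),

   fitted by MCMC without (`fit_zib()`) or with (`fit_zib_icar()`) an
   intrinsic CAR spatial random effect ρ over the queen-neighbour grid.
   A stepwise protocol selects environmental then human-impact covariates
   (`select_covariates()`); convergence is monitored with the
   Gelman–Rubin diagnostic and model fit with percentage of deviance
   explained against a saturated reference.
3. **Range derivation** — probability-of-presence maps are binarized at
   the threshold maximizing the True Skill Statistic
   (`optimal_threshold()`, `derive_range()`), for the posterior-mean map
   and its 2.5%/97.5% quantile maps.
4. **Density and trends** — half-normal distance sampling with a
   survey-period covariate on the scale (`fit_halfnormal_mcds()`),
   nest-to-individual conversion via nest production and decay
   (`nests_to_gorillas()`), and encounter-rate trend arithmetic
   (`trend_row()`, `aggregate_decline()`, `combined_site_decline()`).
5. **Abundance** — density is calibrated against nest encounter rate by
   regression across reference sites (`fit_density_regression()`),
   averaged with area weights, and multiplied by the range area with
   conservatively combined 95% bounds (`estimate_abundance()`).

A synthetic-data module (`simulate_landscape()`, `simulate_effort()`,
`simulate_tracks()`, `simulate_transects()`, `simulate_sites()`) generates
landscapes with known suitability, spatial field, occupancy and detection
truth, so every stage is testable end-to-end without any field data.

## Worked example

```r
library(occuRange)

spec <- landscape_spec(
  n_rows = 20, n_cols = 25, cell_size = 5,
  covariates = c(tree_cover = "gaussian-blob", elevation = "gradient",
                 dist_deforestation = "white-noise"),
  beta_true = c(-1, 1, 1, -1), v_rho_true = 1, delta_true = 0.11, seed = 42)
truth <- simulate_landscape(spec)

effort <- simulate_effort(truth, n_units = c(2, 50), delta = 0.11,
                          prop_sampled = 0.6, seed = 43)
covs <- truth[, c("cell_id", "tree_cover", "elevation", "dist_deforestation")]

fit <- fit_zib_icar(effort, covs, attr(truth, "grid"),
                    mcmc = mcmc_control(chains = 2, iters = 4000,
                                        burn = 2000, thin = 4),
                    seed = 44)
tidy(fit)
#> # A tibble: 6 × 6
#>   term               estimate std.error conf.low conf.high  rhat
#>   <chr>                 <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 (Intercept)          -1.32    0.257    -1.84      -0.856  1.01
#> 2 tree_cover            0.967   0.518    -0.0551     1.94   1.07
#> 3 elevation             1.34    0.562     0.327      2.54   1.05
#> 4 dist_deforestation   -1.21    0.257    -1.72      -0.739  1.01
#> 5 delta                 0.112   0.00613   0.101      0.126  1.00
#> 6 V_rho                 6.64    2.13      2.48       9.85   1.03
```

The detection probability is recovered almost exactly (posterior mean
0.112 against a generative 0.11: roughly one sign record per nine 1-km
walks through occupied habitat), the suitability coefficients carry the
right signs and magnitudes, and `rhat` near 1 indicates the two chains
agree.

```r
obs <- as.integer(effort$y > 0)
idx <- match(effort$cell_id, fit$theta_map$cell_id)
opt <- optimal_threshold(fit$theta_map$theta_mean[idx], obs)
rng <- derive_range(fit$theta_map, opt$threshold)
rng
#> <range_map> mean: 168 presence cells, 4200 km2 (threshold 0.46)

sites <- simulate_sites(n_sites = 9, seed = 45)
reg <- fit_density_regression(sites)
reg
#> <density_reg> density = 0.0142 + 0.1602 * e-rate (9 sites, adj R2 = 0.963)

wrate <- weighted_mean_density(sites$encounter_rate, sites$area_km2)
dens <- predict_density(reg, tibble::tibble(encounter_rate = wrate))
estimate_abundance(range_area(rng),
                   c(dens$density_lwr, dens$density_pred, dens$density_upr))
#> # A tibble: 1 × 6
#>       n n_lower n_upper n_exact area_km2 density
#>   <dbl>   <dbl>   <dbl>   <dbl>    <dbl>   <dbl>
#> 1   700     550     790    671.     4200   0.160
```

Reading the result: the probability threshold with the best skill at
separating detected from undetected cells is 0.46; cells exceeding it
cover 4,200 km². The nine-site calibration of density on nest encounter
rate is tight (adjusted R² 0.963), predicts an area-weighted density of
0.160 individuals km⁻² (95% interval 0.131–0.189), and the combined
estimate is ~700 individuals (550–790). `autoplot(fit)`,
`autoplot(rng, fit)` and `autoplot(reg)` draw the probability map, the
range map, and the calibration.

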