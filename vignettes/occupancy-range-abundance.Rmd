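---
title: "Occupancy, range and abundance estimation from sign-survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy, range and abundance estimation from sign-survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

occuRange implements a pipeline for estimating the distribution range and
population size of an elusive forest species — built around great-ape
nest-sign surveys — when systematic survey designs are impossible and the
available data are opportunistic: ranger-patrol tracks, reconnaissance
walks and a limited number of line transects. This vignette describes the
models, the choices behind them, and what the package's synthetic-data
tests do and do not demonstrate.

## The occupancy model

The landscape is divided into square grid cells (5 km by default,
approximately one gorilla home range). Survey tracks are cut into 1-km
units within each cell; each unit either records sign of the species or
does not. Cell $i$ contributes $n_i$ units with $y_i$ detections, and the
model separates *suitability* from *detectability*:

$$
y_i \sim \text{Binomial}(n_i,\; z_i\,\delta), \qquad
z_i \sim \text{Bernoulli}(\theta_i), \qquad
\operatorname{logit}(\theta_i) = x_i^\top \beta \;(+\; \rho_i).
$$

The zero-inflated binomial (ZIB) mixture accounts for imperfect detection:
a cell with no sign may be truly unsuitable ($z_i = 0$) or suitable but
missed (probability $(1-\delta)^{n_i}$). Detection $\delta$ is constant
across replicates and cells: replicates are 1-km walks made with the same
protocol around the same time, so per-unit detectability is assumed
homogeneous (hooks for detection covariates exist in the design but are
deliberately off).

The spatial variant adds an intrinsic conditional autoregressive (iCAR)
random effect on the logit scale: given its queen neighbours $N(i)$ (up to
8 cells sharing an edge or corner),

$$
\rho_i \mid \rho_{N(i)} \sim \mathcal{N}\!\left(\bar\rho_{N(i)},\;
V_\rho / |N(i)|\right),
$$

sum-to-zero constrained so the intercept stays identifiable. The iCAR term
absorbs spatial aggregation that covariates cannot explain — social
grouping, barriers, unmeasured habitat — and is what allows interpolation
of suitability into unsampled cells from sampled neighbours.

Priors are vague: $\beta_j \sim \mathcal{N}(0, 10^6)$ and
$V_\rho \sim \text{Uniform}(0, 10)$; $\delta$ carries a uniform (Beta(1,1))
prior. The coefficient prior variance is configurable
(`prior_beta_var`); any sufficiently vague value is operationally
equivalent here.

### Sampling scheme

`fit_zib()` / `fit_zib_icar()` run a partially collapsed
Metropolis-within-Gibbs sampler (implemented in C++):

* $\beta$: component-wise random-walk Metropolis against the likelihood
  with $z$ *marginalized analytically* (the per-cell mixture
  $\theta_i\,\text{Binom}(y_i \mid n_i, \delta)$ for $y_i > 0$ and
  $(1-\theta_i) + \theta_i (1-\delta)^{n_i}$ for $y_i = 0$). Proposal
  scales adapt toward ~44% acceptance during burn-in only.
* $\rho$: single-site sweep over *all* landscape cells using the CAR full
  conditional as proposal — a pure Gibbs draw for cells without data, a
  Metropolis accept/reject against the marginalized likelihood for sampled
  cells. The field is recentred each sweep and the shift absorbed into the
  intercept.
* $z$: refreshed from its exact Bernoulli full conditional
  ($\operatorname{logit} P(z_i = 1 \mid y_i = 0) = \operatorname{logit}\theta_i + n_i \log(1-\delta)$).
* $\delta$: conjugate Beta draw given $z$ (exact Gibbs — mixes strictly
  better than a Metropolis step on $\operatorname{logit}\delta$ and targets
  the same posterior).
* $V_\rho$: truncated inverse-gamma full conditional.

Collapsing $z$ out of the $\beta$ and $\rho$ updates matters numerically:
with conditional updates, a chain that wanders to
$\theta \approx 1$ (always possible under a vague coefficient prior) makes
$P(z_i = 1)$ round to 1 in double precision, after which no cell can flip
back and the chain is absorbed on a likelihood plateau. The marginalized
updates have no such trap. A related caveat is statistical rather than
numerical: with few cells and few replicates the vague prior leaves
genuine posterior mass on a "suitable everywhere, rarely detected"
plateau; no sampler fixes that — only more data does.

Defaults are 2 chains, 10,000 iterations, 5,000 burn-in, thinning 5, from
overdispersed starts ($\beta \sim \mathcal{N}(0,1)$,
$\delta \sim U(0.05, 0.95)$); convergence is summarised by the
Gelman–Rubin $\hat R$ per parameter with a warning above 1.1. All
configurable through `mcmc_control()`.

### Predictions, deviance, covariate selection

Because $\rho$ is carried for every landscape cell inside the MCMC,
probability-of-presence maps (`predict_theta()`) include the spatial
effect everywhere: unsampled cells draw their $\rho$ from the CAR
conditional of their neighbours at every sweep, which is posterior kriging
rather than a post-hoc neighbour average. Isolated cells (no neighbours)
get $\rho = 0$.

The reported deviance is the posterior mean of
$-2\log p(y \mid \beta, \delta, \rho)$ with $z$ marginalized. The
saturated reference for `deviance_explained()` fits one free detection
probability per sampled cell at its MLE $y_i/n_i$ — "as many parameters as
observations".

`select_covariates()` reproduces the stepwise protocol: Pearson
$|r| > 0.7$ pre-filter (keeping the first of each offending pair in input
order — a deterministic tie-break), an environment-only ZIB fit, refit on
the significant terms (zero outside the central 95% credible interval),
addition of human-impact covariates, their significance filter, and a
final ZIB.iCAR fit. Note that the pre-filter is blind to which covariate
is causal: if a true driver is strongly correlated with a nuisance layer
listed before it, the driver is the one dropped.

## Range, calibration and abundance

`optimal_threshold()` scans thresholds on a 0.01 grid and maximizes the
True Skill Statistic (sensitivity + specificity − 1) of
$\hat\theta > t$ against observed presence/absence; ties break to the
smallest threshold. The evaluation set is the sampled (and forced-absence)
cells, with "presence" meaning sign was detected — the only observations
available. `derive_range()` applies strict exceedance
($\theta > t$) and reports the area as presence cells × cell area; for the
lower and upper credibility maps the threshold is re-optimized on each map.

Density comes from a two-step calibration: `fit_density_regression()`
regresses site-level gorilla density (from line-transect distance
sampling) on individual-nest encounter rate by OLS, and the area-weighted
mean density across sites is predicted at the area-weighted mean encounter
rate — for a linear model these are identical, which is how the 95%
interval on the weighted density is obtained (the prediction interval at
that rate). `estimate_abundance()` multiplies the mean-map range area by
the weighted point density (rounded to the nearest 100), and pairs the
2.5% quantities (lower-map area × lower density) and 97.5% quantities for
the bounds — deliberately conservative, wider than exact error
propagation.

### A limitation found by simulation

Two properties of this construction deserve emphasis, both measured with
the package's own synthetic-data tests:

1. **The thresholded area is not the occupied area.** The maps threshold
   the *suitability probability* $\theta$, not the posterior probability
   that a cell is occupied given its data. For a well-calibrated model the
   sum of $\hat\theta$ over cells tracks the number of occupied cells, but
   the set $\{\hat\theta > t\}$ at the TSS-optimal $t$ is typically larger
   than the occupied set when many cells have intermediate suitability.
   The meaningful estimand of the pipeline is therefore the *population
   value of its own statistic* — the area where true $\theta$ exceeds the
   population-TSS threshold.

2. **The combined interval omits threshold-selection variance.** In
   end-to-end simulations (a 40×60-cell landscape, 45% of cells sampled
   with 2–50 one-km units each, detection 0.11, nine calibration sites),
   the combined area × density interval covers that estimand in roughly
   80% of replicates rather than the nominal ≥ 95%: the empirical TSS
   threshold is itself noisy, the resulting area jumps with it, and
   neither the probability-map envelope nor the density prediction
   interval accounts for that source of error. Longer chains do not change
   this — it is a property of the interval construction, not of MCMC
   convergence. Users should read the published-style bounds as indicative
   rather than calibrated.

## Distance sampling and trends

`fit_halfnormal_mcds()` fits a half-normal detection function
$g(x) = \exp(-x^2/2\sigma_p^2)$ to perpendicular nest-group distances by
maximum likelihood, with $\log\sigma_p$ linear in the survey period — the
multiple-covariate distance-sampling idea of sharing the curve shape while
letting the scale differ, so a period with few sightings borrows strength
from a better-sampled one. Effective strip width is
$\int_0^w g$, group density $n_p / (2 L_p \mathrm{ESW}_p)$, nest density
multiplies by mean group size, and weaned-gorilla density divides by nest
production × decay (1 nest per individual per day, 106-day decay, both
arguments). No truncation is applied by default (none is needed for the
synthetic half-normal data; real datasets should truncate outliers), and
the truncation used is always echoed in the fit. Variances combine, on the
CV scale, the between-transect encounter-rate variance, the delta-method
variance of $\hat\sigma_p$ from the inverse observed information, and the
group-size standard error, with log-normal 95% limits — the standard
distance-sampling convention.

Trend arithmetic (`trend_row()`, `aggregate_decline()`,
`combined_site_decline()`) follows the reporting conventions of encounter-
rate monitoring: percent-of-original $100\,r_{\text{final}}/r_{\text{first}}$,
per-year decline $(100 - \text{pct})/\Delta\text{years}$ (calendar-year
difference), percentages rounded to 1 dp for reporting, and an error if
rates from different survey methods (transect vs recce) are compared
without an explicit override.

## The synthetic-data generator

`simulate_landscape()` draws standardized covariate layers (directional
gradients, sums of Gaussian bumps, white noise), a spatial field from the
sum-to-zero Gaussian Markov random field with precision
$(D - W)/V_\rho$ — the proper generative twin of the iCAR prior, sampled
by eigendecomposition on the constraint's orthogonal complement — and
latent occupancy $z_i \sim \text{Bernoulli}(\theta_i)$. Coordinates are
planar km with the origin at the lower-left corner; no geographic CRS
exists in synthetic mode.

`simulate_effort()` draws per-cell replicate counts in [2, 50] (the range
observed in grid-cell patrol data) and detections
$\text{Binomial}(n_i, z_i\delta)$ — the model has no false positives.
`simulate_tracks()` places GPS fixes every ≤ 0.25 km along straight
tracks and drops sign points only in occupied cells as a thinned Poisson
process with per-km intensity $-\log(1-\delta)$, chosen so the probability
of at least one sign per 1-km unit equals $\delta$ — the discretization
under which track processing and the effort generator agree.
`simulate_transects()` draws half-normal perpendicular distances per
period, and `simulate_sites()` couples site densities linearly to
encounter rates with Gaussian noise (defaults: slope 0.16, intercept 0.02,
noise SD 0.01 — chosen so a nine-site calibration attains the very high
adjusted $R^2$ regime reported for real nest-count calibrations).

What the generator does *not* emulate: terrain and access bias in where
patrols walk, temporally dynamic occupancy, sign misidentification (false
positives), GPS error, nest-decay variation between sites, and recce vs
transect detectability differences (a single $\delta$ knob per survey
type). Tests passing on synthetic data therefore demonstrate internal
consistency of the estimators, not robustness to these realities.

## Track processing rules

`build_cell_effort()` cuts each polyline at cell boundaries first, then
into consecutive 1-km units within each cell-segment; residuals under 1 km
are discarded, and unit cutting restarts at every cell boundary and track
start, so no unit spans cells or tracks. Sign is assigned to units by
arc-length position of the sign-flagged fixes. Cells need at least 2 units
to enter the model table (occupancy needs replication); there is no upper
cap — the printed 50 in the source data is an observation, not a rule.
Cell intervals are half-open, so boundary points are never
double-assigned. Chimp sign, when present, is tallied (`y_chimp`) but
never modelled. Multiple visits to a cell across years are pooled into a
single season — a stated single-season simplification. Forced absences
(lakes, settlements, far-outside-range cells) are appended with a
configurable pseudo-effort of 2 units and zero detections.

`standardize_covariates()` uses the sample standard deviation
(denominator $n-1$, matching `sd()`/`scale()` in R) and returns the
transform so predictions reuse the training standardization exactly.

## Numerical choices and test scales

* Threshold grids: 0.01 steps over [0, 1]; ties to the smallest value.
* Unit cutting tolerates 1 nm of floating-point shortfall
  ($\lfloor \ell + 10^{-9}\rfloor$) so exact-km segments are not dropped.
* The iCAR variance draw truncates its inverse-gamma to $(0, V_{\max})$ by
  inverse-CDF sampling; degenerate shapes (tiny fields) leave $V_\rho$
  unchanged for that sweep.
* Half-normal fitting uses Brent (one period) or BFGS (several), with the
  closed-form $\hat\sigma^2 = \sum x^2/n$ as the starting value.

The test suite exercises the samplers at reduced but honest scales, chosen
once: credible-interval coverage over 20 replicate fits on 1,000-cell
landscapes; the model-ladder deviance ordering on a 1,200-cell landscape;
selection consistency over 10 replicates at 1,500 cells; the end-to-end
abundance experiment on 2,400-cell landscapes with 45% sampled. Chains in
tests run 2,000–8,000 iterations against the 10,000-iteration default;
all checks that depend on randomness fix their seeds.
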