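Package: occuRange
Title: Occupancy-Based Range and Abundance Estimation for Elusive Great Apes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating species distribution ranges and population
    sizes from opportunistic sign-survey data collected along patrol tracks,
    reconnaissance walks and line transects. Converts georeferenced survey
    points into spatially replicated detection histories on a regular grid,
    fits hierarchical Bayesian zero-inflated binomial occupancy models with
    and without intrinsic conditional autoregressive (iCAR) spatial random
    effects by MCMC, derives presence/absence range maps via True Skill
    Statistic threshold optimisation, estimates density by half-normal
    distance sampling with a survey-period covariate, calibrates density
    against nest encounter rates by regression, and combines range-area and
    density uncertainty into abundance estimates. A synthetic-landscape
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
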