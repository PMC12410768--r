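Package: bupop
Title: Bottom-Up Bayesian Population Estimation from Micro-Census Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint Bayesian hierarchical modelling of building and population
    counts from micro-census survey clusters, with posterior prediction of
    population over settled ~1 ha grid cells and aggregation of posterior
    draws to operational boundaries such as health areas and health zones.
    Building counts and population densities (people per building) are
    modelled as Poisson-lognormal mixtures with settlement-class-specific
    intercepts, covariate effects and variance terms, fitted by MCMC.
    Includes a synthetic-data generator reproducing the assumed generative
    process, covariate screening and standardization utilities, residual and
    cross-validation diagnostics, and global/local Moran's I tests for
    spatial autocorrelation in model residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    stats,
    utils,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    coda,
    ape,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
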