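Package: svcspde
Title: Spatially Varying Coefficient Models for Productivity-Richness Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the geographic scale dependence of
    productivity-species-richness relationships. Computes dynamic habitat
    indices (annual sum, minimum, and seasonality of gross primary
    productivity) from intra-annual raster time series, applies landscape
    route-retention filters, fits a Bayesian spatially varying coefficient
    regression in which intercept and slope are Matern Gaussian fields
    represented through the stochastic partial differential equation (SPDE)
    finite-element approximation with penalized-complexity priors, and maps
    and classifies relationship forms from posterior credible intervals.
    Includes a seeded synthetic-data generator emulating the statistical
    structure of the analysis so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    interp,
    mvtnorm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    numDeriv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
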