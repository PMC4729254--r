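Package: zipmap
Title: Species Abundance Mapping with Spatial Zero-Inflated Poisson Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping species abundance from zero-inflated,
    spatially correlated count data. Fits a zero-inflated Poisson mixture
    whose prevalence (Bernoulli) and intensity (Poisson) components are
    generalized linear spatial models with spherical or exponential
    covariance, calibrated by Langevin-Hastings Markov chain Monte Carlo
    and Monte Carlo maximum likelihood. Calibrated models are mapped to a
    prediction grid by simple kriging with an external drift with a
    second-order Taylor backtransform, and maps are validated by
    leave-one-out cross-validation. Includes a synthetic survey generator
    emulating a square sampling grid with supplementary half-spacing
    points, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
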