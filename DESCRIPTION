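Package: avascale
Title: Avalanche Scaling Analysis in Subsampled Critical Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of neuronal avalanche scaling in a
    critically balanced excitatory-inhibitory network of stochastic
    integrate-and-fire neurons with all-to-all connectivity. Provides an
    exact population-count simulator with coupled hypergeometric
    subsampling, avalanche extraction under coincident-firing thresholds
    and temporal coarse-graining, double power-law fits of mean avalanche
    size versus duration, truncated power-law exponent estimation for size
    and duration distributions, the crackling-noise prediction and the
    deviation-from-criticality coefficient, threshold-subsampling scaling
    collapse, mean delayed pairwise correlations, and a synthetic
    two-photon-style recording pipeline with lognormal threshold z-scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
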