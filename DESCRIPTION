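Package: odflow
Title: Stratified Gravity and Radiation Models for Origin-Destination Trip
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial-interaction modelling of district-level origin-destination
    (OD) trip matrices such as those aggregated from mobile-phone call data
    records. Implements gravity models whose parameters are stratified by trip
    type (urbanicity of origin and destination, intra- versus inter-regional
    travel, and their cross), with power-law and exponential distance kernels,
    a finite-system radiation model, Bayesian fitting under a Poisson
    likelihood with uninformative Gamma priors, model comparison by the
    Deviance Information Criterion, trip-type accuracy evaluation, and a
    synthetic OD-data generator for validation without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
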