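Package: lakeredox
Title: Redox Reactive-Transport Modelling and Gene-Constrained Calibration for a Stratified Lake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing biogeochemical cycling in a seasonally
    stratified lake. Provides a balanced redox reaction network including
    nitrate-coupled sulfide and methane oxidation, a one-dimensional
    diffusion-reaction water-column model, a stochastic sequential
    calibration algorithm driven jointly by chemistry profiles and
    functional-gene relative abundances, an abundance-plus-taxonomy metric
    linking 16S rRNA OTUs to metagenome-assembled genomes, in-silico
    process-knockout and parameter-sweep experiments, and seed-reproducible
    synthetic data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
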