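Package: stickysaxs
Title: Sticky-Hard-Sphere SAXS Models for Protein-Bridged Nanoparticle
    Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative small-angle X-ray scattering (SAXS) models for the
    aggregation of small silica nanoparticles bridged by an adsorbing protein
    such as lysozyme. Implements polydisperse sphere form factors under a
    local monodisperse approximation, the Baxter sticky-hard-sphere structure
    factor with a Gaussian-smeared protein "spacer" radius, a mass-fractal
    aggregate term, Monte Carlo inversion of a measured curve into a discrete
    sphere-size distribution, bounded least-squares fitting of single frames
    and warm-started fitting of millisecond-resolution frame series, a
    synthetic-data simulator for method validation, and stoichiometric
    composite metrics. All user-facing functions take and return tibbles;
    fitted objects have tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
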