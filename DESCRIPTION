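Package: dexct
Title: Dual-Energy MV-kV Computed Tomography Simulation and Estimation-Theoretic Image Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing dual-energy computed tomography with megavoltage
    and kilovoltage X-ray spectra. Provides a Cramer-Rao lower bound engine that
    computes basis-material signal-to-noise ratio for a single polychromatic line
    integral under a fixed dose budget split between two spectra, and a fan-beam
    polychromatic CT simulator with Siddon raytracing, compound-Poisson noise,
    sinogram-domain two-material Gauss-Newton decomposition, filtered
    backprojection, virtual monoenergetic image synthesis, beam-hardening
    correction, and contrast-to-noise / root-mean-square-error evaluation.
    Includes synthetic X-ray spectrum generators, packaged mass-attenuation
    tables, and a parametric pelvis phantom with optional metal hip prosthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
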