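Package: tfusatt
Title: Transcranial Focused Ultrasound Attenuation Modelling and
    Axisymmetric Helmholtz Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the skull attenuates transcranial
    focused ultrasound (tFUS). Provides a frequency-domain solver for the
    axisymmetric lossy Helmholtz equation with perfectly matched layer
    boundaries and a focused bowl source, an exponential skull-thickness
    attenuation model tau(z) = a * exp(-b * z) identified from simulated
    thickness sweeps by nonlinear least squares, site-to-site intracranial
    pressure prediction, and validation against packaged benchtop phantom
    and simulation measurements for real human skulls. All user-facing
    functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
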