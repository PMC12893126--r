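Package: lasethresh
Title: Dosimetry and Probit Threshold Analysis for Pulsed-Laser Corneal
    Damage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning single-pulse laser exposures of the cornea
    into a minimum-visible-lesion damage threshold: Gaussian-beam knife-edge
    waist estimation, peak and aperture-averaged radiant exposure with
    quadrature uncertainty propagation, maximum-likelihood probit (log-normal
    threshold) dose-response fitting with ED50 and Fieller fiducial limits,
    logarithmic lesion-depth regression, and safety-margin comparison against
    ANSI Z136.1 maximum permissible exposure limits.  A synthetic-data
    generator reproduces the statistical structure of a threshold study so
    the whole chain is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
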