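Package: ovaspec
Title: Hyperspectral Transmittance Chemometrics for Egg S-Ovalbumin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Calibration and mapping pipeline for predicting S-ovalbumin
    content of eggs from visible/near-infrared hyperspectral transmittance
    cubes. Provides white/dark reference calibration, region-of-interest
    segmentation and mean-spectrum extraction, standard normal variate (SNV)
    scatter correction, SPXY calibration/prediction partitioning, partial
    least squares regression (PLSR) and least-squares support vector machine
    (LSSVM) models with cross-validated hyperparameter selection, competitive
    adaptive reweighted sampling (CARS) feature-wavelength selection, and
    pixel-wise chemical concentration maps. A seeded synthetic-data module
    emulates the statistical structure of egg transmittance cubes and
    spectrophotometric reference chemistry so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
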