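Package: eggspec
Title: Vis/NIR Transmittance Spectroscopy for Detecting Abnormal Chicken Eggs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, calibration, preprocessing, classification and
    wavelength selection for visible/near-infrared transmittance spectra of
    chicken eggs. Generates synthetic candling spectra with hemoglobin and
    protoporphyrin-IX absorption features, converts raw intensities to relative
    transmittance against white/dark references, applies standard chemometric
    pretreatments (normalisation, SNV, MSC, Savitzky-Golay derivatives), fits
    three-class PLS-DA models to discriminate normal, bloody and yolk-destroyed
    eggs, and reduces the wavelength grid to a handful of informative bands via
    weighted regression coefficients, sequential feature selection, the
    successive projections algorithm and forward stepwise regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
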