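Package: mibgcal
Title: Phantom-Based Calibration and Standardization of Cardiac 123I-MIBG
    Heart-to-Mediastinum Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-calibrating planar cardiac 123I-MIBG
    scintigraphy across gamma-camera/collimator systems. Provides a digital
    calibration phantom with designated heart-to-mediastinum ratios (HMR), a
    simplified planar simulator capturing collimator geometric blur and
    529-keV septal-penetration haze, automated phantom ROI placement and HMR
    quantification, conversion-coefficient computation and standardization of
    HMR to a medium-energy-collimator reference scale, a multicenter phantom
    database quality-control and aggregation pipeline, clinical
    reclassification analysis via net reclassification improvement (NRI),
    and synthetic database generators so the full pipeline is testable
    without external data.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
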