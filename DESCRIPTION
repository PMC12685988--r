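Package: crushcurve
Title: Compression Mechanics of Calcified Aortic Valve Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo uniaxial compression testing of
    calcified nodules resected from stenotic aortic valves. Converts raw
    load-displacement machine recordings into contact-ratio-corrected
    stress-strain curves, computes Compression Strength (peak stress) and
    Compression Energy (area under the curve) at specified strain levels,
    classifies crush patterns as three-phase (elastic ramp, serrated
    plateau, densification) or gradual, extracts nodule CT density from
    maximum-intensity-projection slabs, and produces cohort quartile
    tables, correlation and contingency analyses. Includes a synthetic
    crush-curve and CT-phantom generator emulating the testing-machine
    characteristics so the full pipeline is testable without specimens.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    readxl,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
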