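Package: ldfsim
Title: Simulation and Spectral Processing for Rodent Ocular Laser Doppler Flowmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based synthesis of laser Doppler flowmeter (LDF)
    photocurrent signals for bench scenes (rotating wheel, capillary
    microsphere flow) and rat-eye scenes (retinal artery, optic nerve head),
    together with the instrument's spectral processing chain that turns raw
    photodetector traces into DC, velocity (first spectral moment) and volume
    (DC-squared normalised spectral power) at 14 samples per second with
    quality control. Includes the validation and repeatability toolkit used
    for such instruments: linearity checks, per-subject variation
    coefficients, single-measure two-way random absolute-agreement intraclass
    correlation with confidence intervals, exact Wilcoxon signed-rank tests,
    and end-to-end experiment drivers for baseline, repeatability,
    intraocular-pressure clamp and heart-arrest protocols on synthetic
    cohorts.
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
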