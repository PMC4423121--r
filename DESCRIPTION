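Package: mtarray
Title: Quantification of Paraxial Microtubule Arrays from Track and Trace Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of microtubule organisation in elongating
    cells and in reconstituted assays, working from tabular microscopy-derived
    data (filament polyline traces, plus-end comet tracks, photoactivated-mark
    trajectories, filament-encounter geometries, gliding-assay tracks,
    density-gradient fraction profiles and cell morphology records). Implements
    the Kuiper alignment statistic for angle distributions relative to the cell
    axis, displacement-threshold detection and classification of microtubule
    sliding events, decomposition of fluorescence dissipation into
    depolymerisation, transport and bleaching rates with exponential half-life
    fitting, zippering-versus-crossing classification of dynamic filament
    encounters, gliding speed and bundle-survival analysis, sedimentation
    coefficient calibration with frictional-ratio computation, and cell
    elongation/fusion scoring. A seeded synthetic-data generator emulates every
    input class with ground-truth labels so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
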