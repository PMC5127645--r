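Package: organoidr
Title: Quantitative Analysis of Organoid Drug-Response Imaging and Viability Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis stack for patient-derived organoid pharmacology
    experiments: 3D live/dead nuclear image quantification (thresholding,
    particle detection, size-based alive/dead classification, lower-half-of-
    volume integration, depth-coded projections, ramped-threshold auto-
    thresholding, propidium iodide/H2B death ratios), mitosis/apoptosis
    event-trajectory reconstruction and growth-speed fitting, dose-response
    normalization with four-parameter logistic IC50 fitting and Bliss-
    independence synergy matrices, recovery analytics (alamarBlue kinetic
    viability, caliper tumor-volume series, EdU x DNA cell-cycle
    classification), and a ground-truthed synthetic-data generator that
    emulates confocal organoid stacks, drug plates and kinetic reads so the
    whole pipeline is testable end to end.
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
    graphics,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
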