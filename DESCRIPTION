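Package: flagellar
Title: Kinematic and Hydrodynamic Analysis of Flagellar Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for planar flagellar beating recorded from
    head-tethered sperm. Decomposes tangent-angle fields into shape modes by
    proper orthogonal decomposition, estimates the primary oscillation
    frequency of the beat, builds phase-averaged representative beat cycles
    and amplitude envelopes, computes hydrodynamic power dissipation with
    wall-corrected resistive force theory, projects the free-swimming
    trajectory and straight-line velocity a tethered beat would produce, and
    compares beat patterns between groups with a Procrustes measure. Includes
    a synthetic traveling-wave generator with known ground truth so every
    stage is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
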