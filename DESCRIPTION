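Package: equigait
Title: Simulation, Extraction and Reliability Analysis of Equine Gait
    Variables from Extremity-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the reliability of inertial measurement unit
    (IMU) based equine gait analysis at trot. Simulates six-sensor IMU
    sessions (metacarpal, metatarsal and tibial placements) with programmable
    limb phasing, stride timing, ranges of motion and sensor noise; extracts
    the standard temporal and spatial gait variables (stride duration, limb
    phasing by circular cross-correlation of the lateromedial rotation
    velocity, protraction/retraction event timing, sagittal and coronal
    ranges of motion, hock symmetry); and quantifies inter- and
    intra-evaluator reliability through repeated-measures ANOVA mean squares,
    variance components, interclass/intraclass correlation coefficients and
    variance partitioning coefficients, including an evaluator-experience
    effect test and full blinded-study orchestration.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
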