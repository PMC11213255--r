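Package: leaflapse
Title: Leaf Hyponasty Kinematics from Time-Lapse Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Low-cost leaf phenotyping from side-view time-lapse image
    sequences of a single rosette leaf. Tracks three landmarks (rosette
    center, petiole-lamina junction, leaf tip) through day and night frames
    with an adaptive-template normalized cross-correlation localizer,
    converts pixel trajectories to petiole, lamina and leaf angles and
    lengths in degrees and millimetres, derives baseline-relative kinetics,
    day-night time synchronization, 60-min angular speeds and 2-h binned
    group statistics (ANOVA, Tukey post-hoc, compact letter displays).
    Includes a synthetic leaf-movie generator with exact ground truth so
    every pipeline stage is testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    optparse,
    png,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
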