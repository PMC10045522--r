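Package: seedvigor
Title: Germination Kinetics, ROS Assay Quantification and Expression
    Analysis for Seed Quality Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate seed quality from germination tests and
    noninvasive reactive oxygen species (ROS) assays. Computes the seven
    classical germination indices (germinability, peak value, mean
    germination time and rate, coefficient of velocity, uncertainty and
    synchrony) from daily count time courses; quantifies ROS from
    DCFH-DA fluorescence (baseline-subtracted RFU) and from FOX-1
    absorbance via a fitted hydrogen-peroxide calibration curve with
    inverse prediction; converts qPCR threshold cycles to starting
    quantities (X0 method) with multi-reference normalization and
    control-relative expression; and integrates replicate-level features
    through t-tests, two-way ANOVA with Tukey-Kramer compact letter
    displays, Pearson correlation matrices and standardized PCA. A
    seeded synthetic-data generator emulates the full experimental
    design (hydroprimed, heat-shocked and control seed lots) so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
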