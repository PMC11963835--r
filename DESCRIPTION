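Package: povar
Title: Analysis of Mouse Eye Movements During Off-Vertical Axis Rotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for video-oculography of the mouse vestibulo-ocular reflex
    on dual-axis (pseudo-OVAR) turntables: stimulus kinematics (equivalent
    tilt angle, otolith modulation frequency, head-frame gravito-inertial
    acceleration), pupil detection by threshold segmentation and direct
    least-squares ellipse fitting, fast-/slow-phase nystagmus separation by
    filtered differentiation and acceleration thresholding, sinusoidal
    modulation component (SMC) fitting, bias-velocity and vestibular
    time-constant estimation, clockwise/counter-clockwise fast-phase
    asymmetry statistics, a ground-truthed synthetic data generator for
    every paradigm and lesion scenario, and an executable velocity-storage
    internal model (canal and otolith pathways with tilt-estimator
    feedback) that reproduces the canal dependence of horizontal fast-phase
    nystagmus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    minpack.lm,
    EBImage,
    zoo,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
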