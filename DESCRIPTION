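Package: archgait
Title: Plantar-Pressure Gait Simulation, Arch-Support Biomechanics, and
    Convolutional Gait Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying spring-loaded arch-support (ASA) auxiliary
    treatment of plantar fasciitis at desk scale. Generates synthetic
    18-channel plantar-pressure insole recordings for seven gait patterns,
    builds classification datasets (channel exclusion, windowing,
    normalisation, stratified splitting), trains and evaluates a small
    convolutional neural network for gait recognition, models the
    arch-support spring and the inverted-pendulum walking dynamics with
    heel-strike impulse, computes pressure-relief statistics and electrical
    energy-harvesting quantities, and runs a closed-loop streaming
    warning/feedback stage with session reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
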