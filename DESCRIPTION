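Package: fanflow
Title: Wing-Fanning Induced Flow and Olfactory Sampling Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the airflow that a wing-fanning insect
    induces around its antennae and for the three-dimensional volume of air it
    samples for odour molecules. Reconstructs flapping-wing kinematics
    (stroke-plane, positional, elevation and feathering angles, spanwise angle
    of attack) from 3D landmark trajectories, interpolates time-periodic
    gridded velocity fields in space and time, traces pheromone particles
    backward in time from a virtual antenna, and summarises the resulting
    sampling volume as head-relative distance and angle distributions. A
    synthetic-data generator provides landmark tracks from a parametric
    kinematics model and analytic incompressible flow fields, so the whole
    pipeline is testable without video or CFD inputs.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
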