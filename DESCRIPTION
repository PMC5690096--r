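Package: mrsimqa
Title: Phantom-Based Quality Assurance Analytics for MR Simulators in Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative characterization and routine quality-assurance (QA)
    analysis for magnetic resonance simulators dedicated to radiation therapy
    planning. Provides synthetic phantom generators with known ground truth
    (capsule-grid distortion phantoms, uniform spheres with programmed field
    inhomogeneity, crossed-ramp slice-thickness inserts, multi-compartment
    multi-echo tissue phantoms, respiratory motion phantoms) together with the
    matching analyses: 2D/3D geometric distortion mapping from matched marker
    centroids, dual-echo B0 field homogeneity via phase-difference analysis
    with quality-guided unwrapping, spatial and volumetric fidelity checks,
    amplitude-triggered 4D-MRI acquisition simulation with duty-cycle and
    motion-envelope metrics, two-point Dixon water/fat separation with
    ultrashort-echo-time (UTE) bone enhancement, and tolerance bookkeeping
    for daily and monthly QA reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
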