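Package: o17mri
Title: Simulation and Analysis of Dynamic Oxygen-17 Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic oxygen-17 (17O) magnetic resonance imaging of the
    brain at desk scale: a labeled digital brain phantom with three-phase
    17O2-inhalation kinetics, a density-adapted 3D radial k-space acquisition
    simulator with spoiled steady-state and T2* relaxation weighting,
    sliding-window convolution-gridding reconstruction with Hamming apodization
    and zero-filling, point-spread-function simulation with FWHM, effective
    resolution and T2* signal-bias reporting, geometric-transfer-matrix (GTM)
    partial-volume correction of regional means, and region-of-interest
    time-course statistics (baseline normalization, switch-point averaging,
    baseline variability, mirrored control regions, ventricle-margin exclusion,
    Dice agreement, and relative signal-increase maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    rlang,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
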