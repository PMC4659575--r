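Package: atriamech
Title: Multiscale Electromechanical Modelling of the Human Atria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for human atrial electromechanics at cell and desk-scale
    tissue level. Couples the Courtemanche-Ramirez-Nattel human atrial action
    potential model to the Rice myofilament contraction model through dynamic
    troponin calcium buffering, with regional ionic heterogeneity profiles and
    atrial-fibrillation electrical remodelling factors. Provides pacing
    protocols and biomarker extraction (APD90, calcium transient, sarcomere
    shortening, active force), a deformation-aware monodomain reaction-diffusion
    solver on 1D cables and 2D fibred sheets with Strang splitting and
    Crank-Nicolson diffusion, re-entry induction by cross-field S1-S2
    stimulation, and continuum active-strain mechanics kernels (multiplicative
    deformation decomposition, Guccione strain energy, homogeneous incompressible
    active contraction, divergence-theorem cavity volumes on triangulated
    surfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    readr,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
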