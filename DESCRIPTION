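Package: mwaplan
Title: Microwave Ablation Treatment Planning by Coupled Electromagnetic and Bioheat Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microwave ablation (MWA) of liver tumors with a multi-slot
    coaxial antenna at 2.45 GHz and selects treatment parameters. Generates
    synthetic tumor phantoms or reads segmented surface meshes (STL/PLY),
    voxelizes tumor and antenna into a labeled grid, computes the volumetric
    electromagnetic heat source from an axisymmetric frequency-domain Helmholtz
    solve (or a fast analytic slot-source model), integrates the Pennes bioheat
    equation with evaporation-corrected effective heat capacity and
    damage-dependent blood perfusion, accumulates the Arrhenius thermal damage
    integral, and derives necrosis masks, coverage and safety-margin metrics,
    ablation-time-versus-power curves and the minimal input power that fully
    ablates the tumor within a time budget.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
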