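Package: atrialwave
Title: Monodomain Atrial Fibrillation Simulation and Wave-Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico laboratory for studying atrial fibrillation (AF)
    wave-dynamics on idealized left-atrial tissue. Implements the
    Courtemanche-Ramirez-Nattel human atrial action potential model with
    composable conductance-scaling presets for AF electrical remodeling,
    fibrosis, and flecainide; monodomain reaction-diffusion propagation on
    triangulated sheets with anisotropic conduction and conduction-velocity
    calibration; virtual pulmonary vein isolation lesion sets with and
    without 2-mm conduction gaps; and the analysis stack used to compare
    interventions: dominant-frequency mapping via power spectral density,
    spatial DF heterogeneity (COV-DF), AF cycle length, restitution-slope
    (Smax) mapping, outcome classification (sustained AF, termination,
    conversion to atrial tachycardia), and phase-singularity-based
    wave-break detection at lesion gaps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
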