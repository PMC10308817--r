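Package: abfer
Title: Restraints and Standard-State Corrections for Absolute Binding
    Free Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects receptor-ligand restraints (Boresch, multiple-distance,
    flat-bottomed) from molecular dynamics trajectories by minimum-variance
    ranking, computes the standard-state free energy of releasing a decoupled
    restrained ligand by analytic, numerical-quadrature, rigid-body grid and
    Monte Carlo routes, and assembles per-stage free energy contributions into
    standard binding free energies with symmetry corrections, binding-pose
    combination and replicate aggregation. Includes a synthetic-trajectory
    generator for testing selection and fitting, and trajectory diagnostics
    (binding-site water occupancy, restrained degree-of-freedom time series,
    RMSF).
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
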