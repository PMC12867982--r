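Package: lidfold
Title: Ensemble Thermodynamics of Ligand-Induced Folding of a Disordered
    Protein Lid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis chain for folding-upon-binding of an
    intrinsically disordered protein segment (modelled on the MDM2 'lid')
    driven by a single residue-ligand non-polar contact. Provides a
    coarse-grained two-basin torsion model with Metropolis sampling and
    umbrella-sampling window generation; WHAM, multistate-reweighting (MBAR)
    and variational spline estimators for 2D free-energy surfaces over lid
    extension and lid-core dihedral collective variables; per-residue
    secondary-structure, helix-propensity, RMSF and solvent-accessible
    surface-area observables; nearest-neighbour conformational and ligand
    roto-translational entropy estimators; one-site and competitive-
    displacement isothermal titration calorimetry models with fitting; and
    chemical-shift perturbation, secondary-shift and heteronuclear-NOE
    profiles from NMR shift tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    minpack.lm,
    splines,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    broom,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
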