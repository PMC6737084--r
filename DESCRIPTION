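Package: ercoupler
Title: Helix-Coupling, Dissociation-Barrier and Screening Diagnostics for
    Estrogen-Receptor Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for diagnosing mutant estrogen-receptor-alpha
    (ERa) activation state and antiestrogen behaviour from molecular-dynamics
    trajectories. Computes atomic covariance and Pearson cross-correlation
    (DCCM) matrices, noise-filtered inter-helix correlation scores and
    per-residue coupling profiles; RMSD, greedy RMSD-cutoff (Daura)
    conformational clustering and hydrogen-bond occupancy statistics; a
    standard (fixed-height) metadynamics engine over coordination-number and
    centre-of-mass-distance collective variables with Gaussian hill
    deposition, harmonic walls, free-energy-surface reconstruction,
    lowest-saddle barrier extraction and replica-based uncertainty; and
    virtual-screening utilities (Lipinski and rotatable-bond filters,
    multi-conformation consensus selection, ligand efficiency). Ships seeded
    synthetic-data generators with known ground truth for every input class,
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
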