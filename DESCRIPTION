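Package: statescan
Title: Activation States, Conformational Landscapes and Umbrella-Sampling
    Free Energies for Receptor Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory and free-energy analysis for G protein-coupled
    receptor simulations. Computes activation-state metrics (C-alpha
    distance series, the A100 activation index and its two- and
    three-state classifications, RMSD and per-residue RMSF), extracts
    conformational landscapes by loop-masked mass-weighted principal
    component analysis with k-means clustering and reference-state
    comparison, and estimates potentials of mean force from
    umbrella-sampling windows with a self-consistent WHAM solver,
    Bayesian-bootstrap uncertainties, binding free energies and Boltzmann
    subpocket occupancy ratios. A synthetic-data module generates toy
    receptors, two-state collapse trajectories and umbrella samples from
    analytic potentials with known ground truth, so the full pipeline is
    testable without a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
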