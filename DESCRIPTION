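Package: mdhotspot
Title: Molecular Dynamics Trajectory Analysis and Binding Hot-Spot Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-docking and post-molecular-dynamics analysis toolkit for
    identifying isoform-selective binding hot spots in protein families such
    as the sirtuin (SIRT) deacetylases. Implements trajectory stability
    metrics (Kabsch-superposed RMSD, per-residue RMSF, radius of gyration,
    Shrake-Rupley solvent-accessible surface area), collective-motion
    analyses (essential-dynamics PCA and dynamic cross-correlation matrices
    with percentage-area classification), DSSP-style secondary-structure
    timelines with structured-residue bookkeeping, GROMOS (Daura)
    conformational clustering, geometric hydrogen-bond detection with
    percentage occupancy, and a three-evidence consensus that combines
    docking interaction occurrence counts, H-bond occupancy and per-residue
    energy-decomposition tables into a ranked hot-spot report. A synthetic
    data module generates structures, trajectories and tables with planted
    ground truth so every analysis stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
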