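Package: corrnet
Title: Correlated-Motion and Dynamical Network Analysis of Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("corrnet", "developers", email = "corrnet@example.org",
           role = c("aut", "cre"))
Description: Trajectory analysis toolkit for studying correlated domain
    motion in proteins: Kabsch superposition with RMSD/RMSF and
    crystallographic B-factor conversion, dynamic cross-correlation maps
    (DCCM), principal component analysis of the Cartesian coordinate
    covariance with k-means and hierarchical clustering of conformers,
    and correlation-weighted dynamical networks with contact-persistence
    edges, Girvan-Newman communities, critical nodes, and
    optimal/suboptimal communication paths.  Includes generators for
    synthetic two-lobe trajectories and planted-community graphs with
    analytically known structure, a multi-model PDB reader/writer, and a
    config-driven end-to-end pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
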