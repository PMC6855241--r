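Package: allopath
Title: Allosteric Communication Analysis for Receptor Dimer Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for allosteric communication between a
    protein-protein interface pocket and an orthosteric pocket in a
    receptor dimer. Builds per-frame protein structure networks with
    interaction-percentage edge weights, computes dynamic
    cross-correlation matrices, searches correlation-filtered shortest
    communication pathways between pockets and tallies their cross-frame
    frequencies. Also provides conformational k-means clustering with
    medoid representatives, interface geometry (centroid distance,
    Shrake-Rupley solvent-accessible surface area, contact area,
    grid-based pocket volume), MM-PBSA component-energy bookkeeping with
    per-residue hot-spot filtering, ROC/AUC virtual-screening enrichment
    evaluation, and a synthetic-data module (Gaussian network model
    ensembles, planted-pathway dimers, active/decoy score sets) that
    supplies analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
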