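Package: pocketensemble
Title: Cryptic-Pocket Opening and Ensemble-Docking Affinity Prediction from
    Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies cryptic-pocket opening in protein conformational
    ensembles and predicts ligand binding affinity by Boltzmann-weighted
    aggregation of per-conformation docking scores over a Markov state model
    (MSM). Implements grid-based (LIGSITE-style) ligand-site pocket volumes,
    rigid-body and iterative ensemble superposition, dihedral featurization,
    tICA with commute mapping, cross-validated clustering scored by rank-10
    VAMP-2, reversible maximum-likelihood MSM estimation, MSM-weighted pocket
    statistics with trajectory bootstrapping, docking-score aggregation to a
    binding free energy, and IC50-to-Ki conversion, together with synthetic
    ensemble generators with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
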