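Package: pepperm
Title: Multi-Level Featurization and Fusion Modelling of Cyclic Peptide
    Membrane Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the log10 passive membrane permeability (cm/s) of
    head-to-tail cyclic peptides from structure. Peptides are featurized at
    three levels: per-atom graph and conformer matrices for a
    structure-enhanced transformer, per-monomer descriptor sequences for a
    (cyclic) one-dimensional convolutional network, and whole-molecule
    descriptors plus Morgan fingerprints for a multilayer perceptron. The
    three branches are fused through a shared layer and trained jointly with
    auxiliary losses; inputs are augmented by SMILES enumeration, conformer
    ensembles and cyclic sequence rearrangement, and predictions are averaged
    over the augmented replicas. Includes a synthetic cyclic-peptide
    generator with a known structure-to-permeability relationship, a
    Kennard-Stone diversity split, descriptor selection utilities, and a
    small command-line interface. Chemistry (SMILES handling, conformer
    embedding, descriptors, fingerprints) is delegated to the RDKit toolkit
    through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    randomForest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
SystemRequirements: Python (>= 3.8) with the rdkit and numpy packages on
    the PATH as 'python' or 'python3'.
Config/testthat/edition: 3
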