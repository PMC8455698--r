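Package: gaann
Title: Graph Angle-Attention Neural Networks for NMR Scalar Coupling Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts NMR scalar coupling constants (J-couplings, Hz) from 3-D
    molecular structure with a graph angle-attention neural network: a dual
    message-passing encoder over the chemical-bond graph and the coupling-pair
    graph, a Karplus-inspired bond-angle attention weight on bond messages,
    multi-head self-attention over coupled atoms, and an MLP decoder. Includes
    readers/writers for XYZ files and the champs-scalar-coupling CSV dialect,
    geometric feature engineering (distances, bond angles, dihedral angles,
    nearest-neighbour geometric angles), a synthetic Karplus-labelled molecule
    generator for desk-scale experiments, training with a one-cycle learning
    rate policy, ablation of the angle mechanisms, and Spearman/PCA
    interpretability analyses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
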