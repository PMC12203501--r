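Package: subloc3d
Title: Knowledge-Enhanced Protein Subcellular Localization from 3D Fluorescence Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-label classification of protein subcellular localization in
    single-cell 3D fluorescence volumes. Provides a dual-branch residual
    encoder that fuses 3D volumes with their 2D z-projections through adaptive
    gating, an asymmetric confidence-weighted classification loss for
    imbalanced and weakly annotated data, joint training with Gene Ontology
    knowledge-graph embeddings (TransE, RotatE, PairRE, ComplEx) under
    category-aware negative sampling, and a protein-identity aggregation loss.
    Ships a synthetic single-cell volume and GO-style knowledge-graph
    simulator, protein-level data splits, and per-class and macro evaluation
    metrics (MCC, F1, Jaccard, average precision, clustering score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
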