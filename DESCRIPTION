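Package: alchemal
Title: Active Learning over Chemical Libraries with Free-Energy Oracles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Iterative active-learning exploration of chemical libraries
    toward high-affinity binders. Provides a fragment-based combinatorial
    library builder (BRICS linkers and termini around a fixed core),
    molecular featurization (descriptor/fingerprint blocks and voxel
    atom-hot grids), binding free-energy oracles (lookup tables, a
    noisy synthetic emulator, and manifests for external engines),
    cross-validation ensembles of multilayer perceptrons trained with
    inverse-frequency-weighted L1 loss, batch-selection strategies
    (greedy, uncertain, mixed, narrowing, weighted-random
    initialization), evaluation metrics (RMSE, Kendall tau, top-N
    recovery, TPR), and synthetic affinity landscapes for testing the
    full loop without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Rcpp,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse
SystemRequirements: python (>= 3.8) with rdkit and scikit-learn on PATH
    for chemistry-dependent and t-SNE functionality
Config/testthat/edition: 3
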