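Package: acrscreen
Title: Anti-CRISPR Protein Prediction from PSSM-Derived Evolutionary Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens protein sequences for anti-CRISPR (Acr) activity using
    evolutionary features extracted from PSI-BLAST position-specific scoring
    matrices (PSSM-composition, DPC-PSSM, PSSM-AC and RPSSM descriptors,
    plus amino-acid and dipeptide composition baselines). Class imbalance
    between the few known anti-CRISPRs and the large pool of phage and
    mobile-genetic-element proteins is handled by a multiple-undersampling
    ensemble of RBF-kernel support vector machines with grid-searched
    hyperparameters, combined by score averaging. Includes the matching
    evaluation protocol (repeated balanced cross-validation, repeated
    balanced independent tests, ranked genome screening reports, ROC/AUC
    and confusion-matrix metrics), seeded synthetic-data generators for
    offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    kernlab,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    e1071,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
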