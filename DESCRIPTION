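Package: dbpmkl
Title: DNA-Binding Protein Prediction with Centered-Kernel-Alignment
    Multiple Kernel Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts DNA-binding proteins from sequence alone. Six
    sequence-derived descriptors (global encoding, multi-scale
    continuous/discontinuous composition-transition-distribution,
    normalized Moreau-Broto autocorrelation, pseudo-PSSM, PSSM average
    blocks, and wavelet statistics of PSSM columns) are turned into RBF
    kernels, fused by a centered-kernel-alignment multiple-kernel-learning
    solver with Laplacian weight smoothing, and fed to a precomputed-kernel
    support vector machine. Includes leave-one-out and k-fold
    cross-validation drivers, the full ACC/SN/SP/MCC/AUC metric battery, a
    synthetic benchmark generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    quadprog,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
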