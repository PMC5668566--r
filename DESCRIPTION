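Package: polytrans
Title: Polysome-Profile Quantification and Translation-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies sucrose-gradient polysome profiles into the fraction
    of ribosomes in polysomes (FRP), relates FRP to mouse phenotype by
    correlation and Ward hierarchical clustering, quantifies protein
    co-sedimentation across gradient fractions, computes translation
    efficiency from paired polysomal/total expression with a permutation
    test for differential TE, runs the delta-delta-Ct qPCR pathway to
    log2 delta-TE, and estimates per-cell and per-axon group effect sizes.
    Ships a synthetic-data generator with analytically known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
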