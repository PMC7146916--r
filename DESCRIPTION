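Package: rhizoquant
Title: Rhizotron Root System Architecture Phenotyping and Quantitative Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based phenotyping of root system architecture in
    rhizotrons: adaptive-threshold segmentation of root images under uneven
    illumination, skeleton-based trait quantification (Kimura length,
    distance-transform diameter and volume, convex-hull solidity, depth,
    median root number, vertical length distribution), exponential growth
    kinetics, and downstream quantitative genetics for clonally replicated
    mapping populations (broad-sense heritability from variance components,
    genetic correlation via reciprocal replicates, Kruskal-Wallis
    single-marker QTL scans with stepwise focal-SNP modelling, and a low
    phosphate tolerance index). Includes a synthetic rhizotron scene and
    marker/phenotype generator with exact ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    ggplot2,
    readr,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
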