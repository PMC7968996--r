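Package: parabind
Title: Binding Preferences and Regulatory Landscapes of Paralogous
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how two paralogous transcription factors
    share a genome: classification of ChIP-seq binding sites into
    preferential and shared classes, annotation of candidate regulatory
    elements from histone-mark rules, discrimination of binding preferences
    from position-weight-matrix and nucleotide-composition features by
    L1-penalized classification and regression, classification of genes into
    preferential/redundant/complementary regulation groups from knockdown
    transcriptomics calls, and calling of promoter-interacting regions from
    Capture-C viewpoint profiles with a distance-decay permutation test.
    Includes a seeded synthetic-data generator so the whole pipeline runs
    and verifies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    glue,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
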