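Package: bilqtl
Title: Genotyping and QTL Mapping for Advanced Backcross Introgression Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing backcrossed inbred line (BIL)
    populations such as advanced backcross crosses between a domesticated
    recurrent parent and a wild donor. Includes a crossing-scheme simulator
    (meiosis, backcrossing, single-seed-descent selfing, sparse
    reduced-representation read counts, trait architectures), parental
    polymorphism identification and noise filtering from pileup-style allele
    counts, a heterogeneous hidden Markov model with distance-dependent
    transition probabilities for calling parental genotype blocks from sparse
    noisy counts, population-wide bin construction, marginal and MC+-penalized
    (additive and epistatic) QTL mapping with cross-validation-averaged tuning,
    discrete-trait fine-mapping by interval algebra, and permutation enrichment
    tests for candidate genes and eQTL overlap.
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
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
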