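Package: qtlbvs
Title: Bayesian Variable Selection for QTL Mapping and Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome regression by Bayesian Variable Selection: a
    two-component normal mixture prior on SNP allele-substitution effects
    (BayesC-pi type, with per-SNP mixture indicators) fitted jointly with a
    pedigree-based polygenic term by Markov chain Monte Carlo.  Includes a
    forward gene-drop simulator of half-sib/full-sib livestock populations
    with linkage-disequilibrium-bearing founder haplotypes and additive,
    imprinted and epistatic QTL; SNP quality control; posterior
    summarisation (inclusion probabilities, Bayes factors, HPD intervals,
    effective sample sizes, heritability); LD-based grouping of associated
    SNPs into QTL regions; and genomic breeding-value prediction for
    unphenotyped individuals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
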