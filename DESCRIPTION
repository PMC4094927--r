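Package: bcpi
Title: Bayes C-pi Whole-Genome Regression for Continuous and Ordered
    Categorical Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression for genomic prediction with the Bayes C-pi
    mixture prior, for continuous phenotypes (linear model) and ordered
    categorical phenotypes (liability threshold model with Metropolis-Hastings
    threshold updates). Includes a simulator of multi-population SNP dosage
    panels with divergent allele frequencies and within-chromosome linkage
    disequilibrium, a quantitative-trait simulator on the liability scale with
    ordinal category mapping, genomic breeding value prediction with pooled
    accuracy, bias-slope and rank-correlation validation statistics, and an
    orchestrator for replicated factorial simulation studies comparing models
    across heritabilities, training sizes and category counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
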