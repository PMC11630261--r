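Package: chromdyn
Title: Chromatin-State Segmentation and Histone-Mark Dynamics for Plant Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of histone-modification ChIP-seq
    peak sets, gene expression and metabolite tables in plants under stress.
    Implements a six-way genomic feature partition with priority-based peak
    annotation, TSS-TTS metagene profiles, chromatin-state segmentation by a
    multivariate Bernoulli-emission hidden Markov model over 200-bp binarized
    mark calls, bivalent (active + repressive) domain calling with reChIP
    validation and permutation nulls, expression stratification with exact
    tie-corrected Wilcoxon rank-sum tests, and control-versus-stress mark
    gain/loss dynamics with expression-concordance classes, fold-change
    correlations, basepair Jaccard variability scores and a differential
    metabolite filter. Ships a synthetic-data generator with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
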