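Package: netdiscrim
Title: Differential Network Analysis of Two-Phenotype Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two tumor phenotypes by integrating gene expression
    profiles with protein-protein interaction networks. Implements greedy
    discovery of discriminative subnetworks scored by binned mutual
    information of averaged z-scored activity, differential hub
    co-expression analysis with permutation tests and Fisher z comparison
    of correlations, cross-dataset reproducibility of differential
    expression rankings, hypergeometric gene-set enrichment, and
    signature-based support vector machine classification. Includes a
    seed-reproducible synthetic data generator with planted differential
    expression, planted discriminative subnetworks and planted
    differentially correlated hubs, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
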