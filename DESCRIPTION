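Package: irda
Title: Interdependent Gene Selection with Redundant-Dependent Analysis and Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multivariate information-theoretic filter for selecting predictive,
    stable candidate genes from high-throughput gene-expression matrices. Expression
    values are discretized around the per-gene mean, gene relevance is measured by
    symmetrical uncertainty, genes are partitioned by exact one-dimensional k-means,
    synergistic feature-pairs are discovered through a joint symmetrical-uncertainty
    threshold estimated from positive joint pairs, redundant members are eliminated
    by a conditional-mutual-information backward pass, and surviving parsimony
    models are aggregated into a ranked candidate gene set. Includes a wrapper-based
    evaluation scheme (leave-one-out k-nearest-neighbour classification scored by
    error rate, AUC and Matthews correlation), Jaccard and relative-weighted-consistency
    stability indices with a leave-one-out stability harness, simplified mRMR, CMIM
    and FCBF reference filters, and a planted-signal synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
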