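Package: debi
Title: Differentially Expressed Biclusters by Frequent Gene-Set Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the DeBi biclustering algorithm for gene expression
    data. Expression matrices are binarized into up- and down-regulation
    indicator matrices, seed biclusters are discovered by iterative maximal
    frequent gene-set mining with a descending support threshold, each seed
    is grown and pruned with one-sided Fisher exact tests against its
    phenotype vector, and the resulting biclusters are filtered for mutual
    overlap. The significance level alpha is selected by maximizing a
    randomization-normalized bicluster score. Also provides a synthetic
    benchmark generator with implanted constant and additive biclusters and
    recovery (Jaccard) and consensus (assignment-based) scores for comparing
    bicluster sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
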