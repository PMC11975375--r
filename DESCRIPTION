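Package: crosspool
Title: Demultiplexing and Comparative Analysis of Cross-Species Pooled
    Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled-droplet single-nucleus RNA-seq experiments in
    which samples from two closely related species are captured together.
    Implements species assignment and cross-species multiplet detection via a
    binned two-Gaussian mixture threshold on secondary-genome read counts, a
    genotype-likelihood sample assigner for pooled individuals, differential
    cell-type abundance and pseudobulk differential expression through
    TMM-normalized negative-binomial generalized linear models, proportion
    based homology mapping of clusters onto reference cell-type labels, and an
    expression-matched permutation test for gene-category enrichment. A
    synthetic-data generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Matrix,
    edgeR,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
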