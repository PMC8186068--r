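Package: methylORA
Title: Bias-Aware Gene Set Over-Representation Analysis for Methylation Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene set over-representation testing for Illumina-style methylation
    arrays that corrects two composition biases of probe-to-gene annotation:
    probe-number bias (genes covered by more CpG probes are more likely to
    contain a significant probe) and multi-gene bias (one CpG annotated to
    several overlapping genes is counted repeatedly in a naive gene overlap).
    Significant CpGs, or CpGs underlying differentially methylated regions,
    are mapped to genes with reciprocal multi-gene weights; a probability
    weighting function is estimated by tricube moving-average smoothing of the
    differential methylation indicator ordered by equivalent CpG count; and
    each gene set is tested with a one-sided Wallenius noncentral
    hypergeometric test whose odds are derived from the weighting function.
    Includes a synthetic-array generator and null-simulation harness for
    type-I error evaluation, plus readers for annotation tables, GMT gene set
    collections and BED/CSV region tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
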