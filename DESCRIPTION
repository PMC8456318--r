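Package: acidsweep
Title: Expression, Co-Expression and Selection-Scan Pipeline for Fruit
    Organic-Acid Divergence
Version: 0.1.0
Authors@R:
    person("Maintainer", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, seedable pipeline for explaining organic-acid
    divergence between two pear varieties: FPKM quantification and
    negative-binomial Wald differential expression, weighted co-expression
    modules (soft-power adjacency, topological overlap, eigengenes,
    module-trait statistics), mutual-rank transcription-factor networks,
    windowed Weir-Cockerham F_ST and a cross-population composite-likelihood
    sweep scan on population genotypes, and the intersection of all layers
    that nominates candidate domestication genes. A synthetic-data module
    generates every input with the statistical structure the analysis
    assumes, so the whole chain is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
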