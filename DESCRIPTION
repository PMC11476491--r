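Package: CallbackSeq
Title: Injury-Rescue RNA-Seq Analysis with Call-Back Gene Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-expression analysis for injury-rescue experimental
    designs: a normal control arm, a chemically injured model arm, and one or
    more treatment arms that may restore expression toward normal. Provides
    negative-binomial Wald testing with method-of-moments dispersion
    estimation and Benjamini-Hochberg FDR control, a three-level "call-back"
    classifier for genes whose injury-induced expression shift is reversed by
    treatment, cross-treatment intersection summaries, hypergeometric
    gene-set over-representation with Bonferroni or BH correction, and
    2^-ddCt qPCR relative expression with RNA-seq concordance metrics. A
    negative-binomial synthetic-data generator with archetype-level ground
    truth supports end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
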