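Package: transegR
Title: Transgressive Segregation Analysis of Time-Course RIL Transcriptomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting transgressive segregation in the
    transcriptomes of recombinant inbred line (RIL) panels profiled by
    time-course RNA-Seq under stress. Implements TMM-normalised log2
    fold-change computation against the pre-stress control, threshold-based
    up/down/constant response classification with UpSet-style exclusive set
    intersections, tracing of each gene's expression pattern to its parental
    origin (complete, parent-like, non-parental), selection of steadily
    upregulated and constitutively expressed gene modules unique to a focal
    genotype, signed Pearson-correlation co-expression networks with
    cohesion/fragmentation metrics across genotypes, and integration of
    miRNA family abundances with their mRNA targets via anti-correlation
    screening. Includes a seeded synthetic-data generator that plants
    inheritance classes, co-expression regimes and repressive miRNA-target
    pairs for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
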