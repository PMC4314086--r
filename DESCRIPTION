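Package: noiseDimorph
Title: Sexual Dimorphism in Gene Expression Noise
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to detect a sexual dimorphism in gene expression noise
    from replicated female/male expression data. Computes paired
    female/male coefficients of variation per transcript or trait cell,
    tests for a sex bias with a Wilcoxon matched-pairs signed-ranks
    statistic against a Monte Carlo permutation null, compares sex-wise
    quadratic regressions of noise on mean abundance, stratifies tests by
    five-state chromatin color via full containment of gene spans in
    single-color tracts, and tests for heterogamety-biased dispersal
    across metazoan species by permuting chromosome-system tags. Includes
    seeded generators for synthetic expression, trait, and dispersal data
    so every stage runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, IRanges,
    GenomicRanges, rtracklayer
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
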