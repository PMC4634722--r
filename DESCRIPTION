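Package: regulonscan
Title: Transcription-Factor Regulon Reconstruction from ChIP Binding and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs bacterial transcription-factor regulons by
    integrating ChIP binding evidence with wild-type versus deletion-mutant
    differential expression. Provides a simplified local-Poisson peak
    caller for IP/input coverage, position weight matrix construction,
    degenerate consensus rendering and two-strand genome scanning, a Gibbs
    sampler for fixed-width motif discovery, a negative-binomial Wald test
    for two-condition count data, rules that classify genes as directly
    regulated, scan-supported candidates, indirectly regulated or
    unaffected, promoter-enrichment statistics, and orthologue-mapped
    cross-species regulon comparison. A synthetic-data module generates
    circular genomes, annotations, planted binding sites, ChIP coverage and
    replicated count matrices with known truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
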