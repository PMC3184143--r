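Package: peakcompare
Title: Comparative Analysis of ChIP-Seq Peak Calls and Their Association
    with Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing peak sets produced by different ChIP-Seq
    peak-calling programs on a shared genome: per-caller summary statistics
    (peak count, union base-pair coverage, bandwidth), base-pair consensus
    support across callers, pileup normalization and per-peak height,
    peak-to-gene classification with strand-aware flanking windows,
    expression discretization by z-score, hypergeometric association tests
    between peak position and expression category, term enrichment with
    Benjamini-Yekutieli adjustment, and evaluation against a gold-standard
    enriched/unenriched gene list. Includes a synthetic-study generator
    (genome, genes, expression, repressive histone-mark domains, Poisson
    read pileups, and distorted virtual-caller peak sets) so the whole
    pipeline is testable end to end, modelled on an H3K27me3 profiling
    study in rice endosperm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
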