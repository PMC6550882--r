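Package: paracis
Title: Parallel Expression Divergence and Cis/Trans Regulatory Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting the regulatory architecture of
    parallel gene-expression divergence between ecotype pairs. Detects
    transcripts with parallel expression divergence via a composite
    principal-component statistic with a label-permutation false discovery
    rate; classifies cis- versus trans-regulatory divergence from
    allele-specific expression in F1 hybrids using binomial exact tests with a
    mapping-bias-adjusted null and Fisher's exact test; quantifies cis/trans
    magnitudes, inheritance mode (dominance/additivity), sibling sharing and
    environmental (salinity) stability of allelic ratios; and scans for
    selection signatures (Weir-Cockerham FST, nucleotide diversity, cluster
    separation score) around transcription start sites. Includes a synthetic
    data generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
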