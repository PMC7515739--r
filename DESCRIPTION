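Package: spaceracq
Title: CRISPR Spacer Acquisition and Phage Escape Analysis from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse Type III CRISPR-Cas spacer acquisition during
    phage infection from expanded-array amplicon reads: repeat-anchored
    extraction of newly acquired spacers, protospacer mapping at an identity
    and uniqueness threshold, strand- and position-bias statistics with
    replicate-overlap and double-spacer selection tests, temporal
    classification of phage genes from expression time courses, and
    deletion-spectrum analysis of CRISPR escaper phages. A synthetic-data
    generator emulates all sequencing inputs (an LTR-bearing phage genome,
    expanded-array amplicons under a tunable selection model, expression
    count matrices, and escaper amplicons with implanted deletions) so every
    stage can be scored against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
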