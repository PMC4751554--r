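Package: chromoscout
Title: Detection, Reconstruction and Classification of Complex Genomic
    Rearrangements from Read Depth and Split Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for characterizing complex genomic
    rearrangements (CGRs) from whole-genome sequencing alignments of a test
    sample against a matched control. Estimates copy-number state from
    normalized windowed read-depth ratios with multi-resolution breakpoint
    refinement, calls breakpoint junctions from clusters of soft-clipped
    split reads with realignment-based partner confirmation, characterizes
    junction microhomology and (templated) insertions, integrates copy
    segments and junctions into a segment graph, enumerates candidate
    derivative-chromosome structures, and classifies the rearrangement as
    chromoanasynthesis-like or chromothripsis-like. Includes a paired-end
    read simulator with truth alignments whose default scenario is a
    duplication/triplication CGR modeled on a rearrangement discovered in a
    Caenorhabditis elegans mutagenesis screen, and an in silico PCR module
    reproducing junction-specific amplification checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
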