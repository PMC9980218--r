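Package: plastedit
Title: Chloroplast C-to-U RNA Editing Analysis from Reads, Traces and PPR Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chloroplast C-to-U RNA editing from aligned RNA-seq
    reads and Sanger trace peak tables, tests for differential editing between
    silenced and control plants with a one-tailed Welch t-test, predicts
    PLS-type PPR protein binding sites on the plastome with a PPR-code position
    weight matrix and exact P-values, and builds neighbor-joining phylogenies
    of PPR orthologs from p-distances with bootstrap support. Ships a
    synthetic-plastome simulator (reference, annotation, planted editing
    fractions, paired-end reads with truth alignments, trace peak tables) so
    the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
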