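Package: mitoscreen
Title: Repeat, Recombination and Transfer Screening for Plant Organellar Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for interrogating plant mitochondrial genome assemblies:
    similarity-based gene annotation with pseudogene, fragment and
    trans-splicing calls; dispersed and tandem repeat detection with a
    long-read proxy for repeat-mediated recombinational activity; screening
    for plastid-derived inserts (MTPTs) and horizontally transferred tracts
    against order-level reference panels; distance-based gene trees with a
    bootstrap grouping test for vertical versus horizontal inheritance; a
    permutation scan for gene conversion; and C-to-U RNA editing prediction
    and transcriptome-based observation. Includes a ground-truthed simulator
    of organellar genomes, long reads and transcript reads for validating
    every screen end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
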