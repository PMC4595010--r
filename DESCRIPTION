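Package: miRquarry
Title: MicroRNA Discovery, Annotation, Quantification and Target
    Scanning from Small-RNA Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering microRNAs in small-RNA
    sequencing data against a transcriptome: adapter trimming, length
    filtering and read collapsing, rRNA/tRNA contaminant removal, exact
    transcriptome mapping, hairpin-precursor location and evaluation under
    explicit structural criteria (matched base pairs, terminal loops,
    nearest-neighbour folding energy), star-strand inference from the
    Dicer duplex geometry, conservation classification against a reference
    mature set, per-strand abundance quantification with a read-count
    cutoff, and a seed-constrained miRNA:mRNA target scan with G:U wobble
    handling.  Ships the printed data tables of a sharpshooter small-RNA
    study as fixtures and a deterministic read simulator, so the whole
    analysis is reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
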