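Package: mitochar
Title: Characterization of Rearranged Avian Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize annotated circular mitochondrial genomes,
    with an emphasis on passerine (leaf-warbler type) genomes carrying a
    duplicated control region. Computes base composition and AT/GC strand
    skews for whole genomes, gene classes and codon positions; relative
    synonymous codon usage (RSCU) under the vertebrate mitochondrial code
    with handling of incomplete stop codons; circular gene-order comparison
    with an exhaustive tandem duplication-random loss (TDRL) explanation
    search; control-region domain partitioning, conserved-box and C-string
    scanning, and tandem-repeat detection; tRNA stem base-pair
    classification and cross-species stem conservation; p-distance matrices
    and neighbor-joining summaries. A synthetic-mitogenome generator with
    full ground-truth bookkeeping makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
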