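Package: intronIT
Title: Intron-Targeting Marker Design for Tracing Alien Chromatin in Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs intron-targeting (IT) PCR markers that distinguish an
    alien chromosome arm (e.g. Haynaldia villosa 4VS) from its wheat
    homoeologs (4AL, 4BS, 4DS). From gene annotations and four genomic
    assemblies the pipeline maps spliced transcripts onto each arm with a
    seed-chain-extend aligner, measures homoeologous intron sizes, selects
    introns whose alien-genome size differs by at least 10 percent from every
    wheat homoeolog, designs exon-anchored primer pairs under melting
    temperature, length and product-size constraints, and validates markers
    by in-silico PCR with gel band-pattern classification and
    translocation-line bin assignment. A synthetic homoeologous-panel
    generator with known ground truth supports end-to-end testing without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
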