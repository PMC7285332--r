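Package: circleseed
Title: Targeted Seed-and-Extend Assembly of Circular Organelle Genomes
    from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Iterative seed-and-extend assembler for small circular
    genomes (plant mitochondria and plastids) from low-error long reads.
    Starting from a seed sequence, reads are aligned to the 3' edge of the
    growing contig, their overhanging parts are collapsed into a consensus,
    and the contig is extended until it circularizes, dead-ends, or forks
    into alternative extensions backed by similar read support. Companion
    utilities cover median k-mer copy-number read filtering to enrich for
    high-copy organellar reads, intra-genome repeat detection, detection of
    mitochondrial inserts of plastid origin, masking of variants in
    plastid-derived regions, and a truth-tracked simulator of multipartite
    circular genomes and long-read sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
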