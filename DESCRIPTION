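Package: wildtx
Title: Transcriptome Characterization of Wild Accessions Against a Reference Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly analysis of strand-specific de novo transcriptomes
    from wild accessions sequenced against an annotated reference genome:
    assembly summary statistics and polyA trimming, filtering of
    strand-orientation assembly artifacts, spliced transcript-to-genome
    alignment and mapping-category classification, redundancy clustering with
    longest-representative selection, coding-potential scoring of distinct
    (unalignable) transcripts, homozygous SNP and small-indel calling from
    read pileups with gene-model effect annotation, cis-natural antisense
    transcript discovery and overlap-geometry classification, and GO term
    over-representation testing. Includes a seeded synthetic-data generator
    that emits a toy reference genome, a diverged accession transcriptome and
    machine-readable truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    data.table,
    stats,
    utils,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
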