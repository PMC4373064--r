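test_that("an exact two-exon transcript aligns as two blocks at identity 1", {
  synth <- small_synth()
  two_exon <- Filter(function(g) nrow(g$exons) == 2L, synth$ref$genes)
  g <- two_exon[[1L]]
  p <- wildtx:::extract_spliced_plus(g, synth$ref$genome)
  tx <- if (g$strand == "-") wildtx:::revcomp(p) else p
  aln <- align_transcripts(c(probe = tx), synth$ref$genome)
  expect_length(aln, 1L)
  a <- aln[[1L]]
  expect_identical(length(a$sizes), 2L)
  expect_identical(a$identity, 1)
  expect_identical(a$strand, g$strand)
  expect_identical(a$tstarts, unname(g$exons[, 1L]))
  expect_identical(a$tstarts + a$sizes, unname(g$exons[, 2L]))
})

test_that("a contig present at two genomic loci yields two alignments", {
  synth <- small_synth()
  dup <- synth$ref$layout$dup
  src <- dup[dup$id == "dup_src", ]
  probe <- substr(synth$ref$genome[[src$chrom]], src$start + 101L,
                  src$start + 500L)
  aln <- align_transcripts(c(probe = probe), synth$ref$genome)
  expect_length(aln, 2L)
  expect_identical(sort(vapply(aln, `[[`, character(1), "chrom")),
                   sort(dup$chrom))
})

test_that("mapping categories on synthetic data equal planted truth exactly", {
  synth <- small_synth()
  m <- merge(synth$acc$truth$mapping, synth$classes, by = "contig_id")
  expect_identical(nrow(m), nrow(synth$acc$truth$mapping))
  expect_identical(m$category.x, m$category.y)
})

test_that("every contig gets exactly one category and order does not matter", {
  synth <- small_synth()
  expect_identical(sort(synth$classes$contig_id), sort(names(synth$kept)))
  expect_false(anyDuplicated(synth$classes$contig_id) > 0L)
  set.seed(2)
  shuffled <- classify_transcripts(synth$kept,
                                   synth$aln[sample(length(synth$aln))],
                                   synth$ref$genes,
                                   chroms = names(synth$ref$genome))
  expect_identical(shuffled[order(shuffled$contig_id), ],
                   synth$classes[order(synth$classes$contig_id), ])
})

test_that("overlap-fraction boundaries split intergenic/small/sense classes", {
  # one plus-strand gene on a toy genome; unspliced probes at controlled
  # overlap fractions
  set.seed(31)
  genome <- c(chr = wildtx:::random_dna(6000L))
  exons <- cbind(start = 2000L, end = 3200L)
  gene <- wildtx:::gene_model("g1", "chr", "+", 2000L, 3200L, exons,
                              cbind(start = 2030L, end = 3128L))
  probes <- c(
    inside = substr(genome[["chr"]], 2101L, 2500L),       # fraction 1
    straddle = substr(genome[["chr"]], 1801L, 2200L),     # fraction 0.5
    outside = substr(genome[["chr"]], 501L, 900L),        # fraction 0
    anti = wildtx:::revcomp(substr(genome[["chr"]], 2101L, 2500L)))
  aln <- align_transcripts(probes, genome)
  cls <- classify_transcripts(probes, aln, list(g1 = gene), chroms = "chr")
  got <- stats::setNames(cls$category, cls$contig_id)
  expect_identical(unname(got["inside"]), "sense_gene")
  expect_identical(unname(got["straddle"]), "small_overlap")
  expect_identical(unname(got["outside"]), "intergenic")
  expect_identical(unname(got["anti"]), "antisense_gene")
  expect_equal(cls$overlap_fraction[cls$contig_id == "straddle"], 0.5)
})

test_that("alignments referencing unknown chromosomes are rejected", {
  synth <- small_synth()
  expect_error(
    classify_transcripts(synth$kept, synth$aln, synth$ref$genes,
                         chroms = "not_a_chrom"),
    "unknown chromosome")
})
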