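mk_aln <- function(contig_id, chrom, strand, tstart, tend, qsize = tend - tstart) {
  wildtx:::transcript_alignment(contig_id, chrom, strand, qsize,
                                qstarts = 0L, tstarts = tstart,
                                sizes = tend - tstart,
                                matches = tend - tstart, mismatches = 0L)
}

test_that("reverse-orientation overlap must strictly exceed 50 bp", {
  set.seed(41)
  # construct a/b with an exact 50 bp reverse-orientation overlap and
  # guaranteed-mismatching flanks
  wrap <- function(core) {
    # A-flanks around the core in a, C-flanks in b: after reverse
    # complementing b the flanks face A-vs-G mismatches on both sides, so
    # the local alignment cannot extend past the planted overlap
    list(a = paste0(wildtx:::random_dna(150L), strrep("A", 30L), core,
                    strrep("A", 30L)),
         b = paste0(wildtx:::random_dna(150L), strrep("C", 30L),
                    wildtx:::revcomp(core), strrep("C", 30L)))
  }
  p50 <- wrap(wildtx:::random_dna(50L))
  expect_identical(nrow(find_antisense_overlaps(c(a = p50$a, b = p50$b))), 0L)

  p51 <- wrap(wildtx:::random_dna(51L))
  res <- find_antisense_overlaps(c(a = p51$a, b = p51$b))
  expect_identical(nrow(res), 1L)
  expect_identical(res$seq_overlap, 51L)

  # sense-identical contigs are not antisense candidates
  s <- wildtx:::random_dna(300L)
  expect_identical(nrow(find_antisense_overlaps(c(a = s, b = s))), 0L)
})

test_that("planted pairs are recovered with matching geometry and pairing", {
  synth <- small_synth()
  labels <- vapply(names(synth$kept), function(id) {
    score_coding_potential(synth$kept[id])$label
  }, character(1))
  cands <- find_antisense_overlaps(synth$kept)
  pairs <- confirm_and_classify(cands, synth$aln, labels)
  truth <- synth$acc$truth$antisense
  key <- function(d) sort(paste(d$contig_a, d$contig_b, d$geometry,
                                d$pairing))
  expect_identical(key(pairs), key(truth))
})

test_that("span geometry follows the strand-aware 3'/5' overlap rules", {
  pairs <- data.frame(contig_a = "a", contig_b = "b", seq_overlap = 100L,
                      stringsAsFactors = FALSE)
  # containment
  aln <- list(mk_aln("a", "c1", "+", 100L, 1000L),
              mk_aln("b", "c1", "-", 300L, 700L))
  expect_identical(confirm_and_classify(pairs, aln)$geometry, "contained")
  # overlap at both 3' ends
  aln <- list(mk_aln("a", "c1", "+", 100L, 1000L),
              mk_aln("b", "c1", "-", 800L, 1500L))
  expect_identical(confirm_and_classify(pairs, aln)$geometry, "tail_to_tail")
  # overlap at both 5' ends
  aln <- list(mk_aln("a", "c1", "+", 800L, 1500L),
              mk_aln("b", "c1", "-", 100L, 1000L))
  expect_identical(confirm_and_classify(pairs, aln)$geometry, "head_to_head")
  # classification is symmetric in the pair order
  rev_pairs <- data.frame(contig_a = "b", contig_b = "a", seq_overlap = 100L,
                          stringsAsFactors = FALSE)
  expect_identical(confirm_and_classify(rev_pairs, aln)$geometry,
                   "head_to_head")
  # coding pairing from member labels
  res <- confirm_and_classify(pairs, aln,
                              c(a = "coding", b = "noncoding"))
  expect_identical(res$pairing, "coding_noncoding")
})

test_that("mirror artifacts and non-co-located pairs are discarded", {
  pairs <- data.frame(contig_a = "a", contig_b = "b", seq_overlap = 100L,
                      stringsAsFactors = FALSE)
  # identical genomic block sets on opposite strands: one transcript
  # assembled twice
  aln <- list(mk_aln("a", "c1", "+", 100L, 700L),
              mk_aln("b", "c1", "-", 100L, 700L))
  expect_identical(nrow(confirm_and_classify(pairs, aln)), 0L)
  # different chromosomes
  aln <- list(mk_aln("a", "c1", "+", 100L, 700L),
              mk_aln("b", "c2", "-", 100L, 700L))
  expect_identical(nrow(confirm_and_classify(pairs, aln)), 0L)
  # same strand
  aln <- list(mk_aln("a", "c1", "+", 100L, 700L),
              mk_aln("b", "c1", "+", 300L, 900L))
  expect_identical(nrow(confirm_and_classify(pairs, aln)), 0L)
  # a member with two qualifying alignments drops the pair with a warning
  aln <- list(mk_aln("a", "c1", "+", 100L, 700L),
              mk_aln("a", "c1", "+", 5000L, 5600L),
              mk_aln("b", "c1", "-", 300L, 900L))
  expect_warning(res <- confirm_and_classify(pairs, aln), "unique qualifying")
  expect_identical(nrow(res), 0L)
})
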