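test_that("identical contigs cluster together with lexicographic tie-break", {
  s <- strrep("ACGTG", 100L)
  cl <- cluster_transcripts(c(b = s, a = s))
  expect_length(cl, 1L)
  expect_identical(cl[[1L]]$representative, "a")
  expect_identical(cl[[1L]]$member_ids, c("a", "b"))
})

test_that("a perfect 80 bp overlap does not meet the 100 bp rule", {
  set.seed(17)
  core <- wildtx:::random_dna(80L)
  a <- paste0(wildtx:::random_dna(150L), core)
  b <- paste0(core, wildtx:::random_dna(150L))
  cl <- cluster_transcripts(c(a = a, b = b))
  expect_length(cl, 2L)
})

test_that("single linkage chains A~B~C into one cluster", {
  set.seed(18)
  left <- wildtx:::random_dna(150L)
  mid <- wildtx:::random_dna(150L)
  right <- wildtx:::random_dna(150L)
  a <- paste0(left, mid)                 # shares mid with b
  b <- paste0(mid, right)                # shares right with c
  c_ <- paste0(right, wildtx:::random_dna(150L))
  contigs <- c(a = a, b = b, c = c_)
  cl <- cluster_transcripts(contigs)
  expect_length(cl, 1L)
  expect_identical(cl[[1L]]$member_ids, c("a", "b", "c"))
  # A and C share nothing directly
  ov <- wildtx:::local_overlap(a, c_)
  expect_false(ov$columns >= 100L && ov$identity >= 0.97)
  expect_identical(brute_clusters(contigs), list(c("a", "b", "c")))
})

test_that("clustering equals the brute-force oracle on synthetic contigs", {
  synth <- small_synth()
  contigs <- synth$kept
  got <- cluster_transcripts(contigs)
  got_sets <- unname(lapply(got, `[[`, "member_ids"))
  want_sets <- brute_clusters(contigs)
  expect_setequal(lapply(got_sets, paste, collapse = ","),
                  lapply(want_sets, paste, collapse = ","))
  # representative is always the longest member (ties -> smallest id)
  for (cl in got) {
    lens <- nchar(contigs[cl$member_ids])
    expect_identical(cl$representative,
                     sort(cl$member_ids[lens == max(lens)])[1L])
  }
})

test_that("planted redundant copies co-cluster with their longer source", {
  synth <- small_synth()
  cl <- cluster_transcripts(synth$kept)
  rep_of <- unlist(lapply(cl, function(x) {
    stats::setNames(rep(x$representative, length(x$member_ids)),
                    x$member_ids)
  }))
  ct <- synth$acc$truth$clusters
  expect_identical(unname(rep_of[ct$contig_id]), ct$cluster_rep)
})

test_that("coding potential score is the documented ORF-length transform", {
  set.seed(19)
  orf600 <- wildtx:::random_cds(600L)
  contig <- c(x = paste0(wildtx:::random_dna(150L), orf600,
                         wildtx:::random_dna(150L)))
  call <- score_coding_potential(contig)
  expect_gte(call$longest_orf_len, 600L)
  expect_gte(call$score, 1.0)
  expect_identical(call$label, "coding")

  # 90 nt ORF with stop-free construction scores -0.7
  orf90 <- wildtx:::random_cds(90L)
  flank <- gsub("ATG", "CCC", wildtx:::random_dna(60L), fixed = TRUE)
  call90 <- score_coding_potential(c(x = paste0("TTTAATTTTAA", orf90)))
  expect_identical(call90$longest_orf_len, 90L)
  expect_equal(call90$score, -0.7)
  expect_identical(call90$label, "noncoding")

  no_atg <- c(x = strrep("CCGTTC", 50L))
  call0 <- score_coding_potential(no_atg)
  expect_identical(call0$longest_orf_len, 0L)
  expect_equal(call0$score, -1)
  expect_identical(call0$label, "noncoding")
})

test_that("distinct sets equal planted truth, split by coding potential", {
  synth <- small_synth()
  cl <- cluster_transcripts(synth$kept)
  distinct <- identify_distinct(cl, synth$classes, synth$kept)
  truth <- synth$acc$truth$distinct
  expect_setequal(distinct$coding,
                  truth$contig_id[truth$coding_label == "coding"])
  expect_setequal(distinct$noncoding,
                  truth$contig_id[truth$coding_label == "noncoding"])

  # missing mapping class for a representative is an error
  expect_error(identify_distinct(cl, synth$classes[-1L, ], synth$kept),
               "no mapping class")
})
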