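test_that("assembly statistics match closed-form fixtures", {
  contigs <- stats::setNames(strrep("A", c(2, 3, 4, 5, 6)),
                             paste0("c", 1:5))
  st <- compute_assembly_stats(contigs)
  expect_identical(st$total_bases, 20L)
  expect_identical(st$n50, 5L)

  one <- c(x = strrep("G", 100L))
  st1 <- compute_assembly_stats(one)
  expect_identical(st1$n50, 100L)
  expect_identical(st1$mean_length, 100)

  expect_equal(compute_assembly_stats(c(a = "ATGCN"))$gc_percent, 50)
  expect_error(compute_assembly_stats(character(0)), "no contigs")
})

test_that("N50 equals the brute-force oracle on random length multisets", {
  set.seed(123)
  for (i in 1:300) {
    lens <- sample(1:80, sample(1:25, 1L), replace = TRUE)
    contigs <- stats::setNames(strrep("A", lens), paste0("c", seq_along(lens)))
    expect_identical(compute_assembly_stats(contigs)$n50,
                     as.integer(brute_n50(lens)))
  }
})

test_that("assembly statistics are invariant to contig order", {
  synth <- small_synth()
  contigs <- synth$acc$contigs
  set.seed(1)
  shuffled <- contigs[sample(length(contigs))]
  expect_equal(compute_assembly_stats(contigs),
               compute_assembly_stats(shuffled))
})

test_that("polyA trimming removes long tails only, 3' end first", {
  t1 <- trim_polya(c(x = paste0("GATTACG", strrep("A", 12L))))
  expect_identical(unname(t1), "GATTACG")
  # below min_run: unchanged
  t2 <- trim_polya(c(x = paste0("GATTACG", strrep("A", 9L))))
  expect_identical(unname(t2), paste0("GATTACG", strrep("A", 9L)))
  # the maximal trailing run includes any terminal genomic A
  t2b <- trim_polya(c(x = paste0("GATTACA", strrep("A", 9L))))
  expect_identical(unname(t2b), "GATTAC")
  # antisense-written tail: leading Ts
  t3 <- trim_polya(c(x = paste0(strrep("T", 11L), "GATTACA")))
  expect_identical(unname(t3), "GATTACA")
  # only one end trimmed per call; 3' checked first
  t4 <- trim_polya(c(x = paste0(strrep("T", 11L), "GATTACG",
                                strrep("A", 11L))))
  expect_identical(unname(t4), paste0(strrep("T", 11L), "GATTACG"))
  expect_warning(t5 <- trim_polya(c(x = strrep("A", 30L))), "dropped")
  expect_null(t5)
})

test_that("strand filter discards below the strict 1/10 boundary", {
  counts <- data.frame(contig_id = c("a", "b", "c"),
                       sense = c(0L, 1L, 100L),
                       antisense = c(5L, 10L, 3L), stringsAsFactors = FALSE)
  res <- filter_strand_artifacts(counts)
  expect_identical(res$discarded, "a")
  expect_setequal(res$kept, c("b", "c"))
  expect_warning(
    res2 <- filter_strand_artifacts(counts, contig_ids = c("a", "b", "c", "d")),
    "missing")
  expect_true("d" %in% res2$kept)
  counts$sense[1] <- -1L
  expect_error(filter_strand_artifacts(counts), "negative")
})

test_that("strand filter removes exactly the planted artifacts", {
  synth <- small_synth()
  expect_setequal(synth$filt$discarded, synth$acc$truth$artifacts$contig_id)
  # boundary contig with sense exactly antisense/10 is kept
  b <- synth$acc$counts[synth$acc$counts$sense * 10L ==
                          synth$acc$counts$antisense, ]
  expect_gte(nrow(b), 1L)
  expect_true(all(b$contig_id %in% synth$filt$kept))
})
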