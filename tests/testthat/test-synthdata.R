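test_that("generation is byte-identical for a fixed seed", {
  cfg <- small_config(seed = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- generate_reference(cfg, dir = d1)
  generate_accession(cfg, r1, dir = d1)
  r2 <- generate_reference(cfg, dir = d2)
  generate_accession(cfg, r2, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("annotation has the configured gene count and valid gene structure", {
  synth <- small_synth()
  expect_length(synth$ref$genes, synth$cfg$n_genes)
  gff <- withr::local_tempfile()
  write_gff3(synth$ref$genes, gff)
  expect_identical(sum(grepl("\tgene\t", readLines(gff))), synth$cfg$n_genes)
})

test_that("every CDS translates to M... with one terminal stop; introns are GT-AG", {
  synth <- small_synth()
  for (g in synth$ref$genes) {
    cds <- wildtx:::extract_cds_seq(synth$ref$genome[[g$chrom]], g$cds,
                                    g$strand)
    prot <- strsplit(wildtx:::oracle_translate(cds), NULL)[[1]]
    expect_identical(prot[1L], "M")
    expect_identical(which(prot == "*"), length(prot))
    introns <- wildtx:::gene_introns(g)
    for (i in seq_len(nrow(introns))) {
      s <- substr(synth$ref$genome[[g$chrom]], introns[i, 1L] + 1L,
                  introns[i, 2L])
      if (g$strand == "-") s <- wildtx:::revcomp(s)
      expect_identical(substr(s, 1L, 2L), "GT")
      expect_identical(substr(s, nchar(s) - 1L, nchar(s)), "AG")
    }
  }
})

test_that("zero planting rates give exact exon concatenations", {
  cfg <- synth_config(seed = 11L, n_genes = 6L, chrom_len = 40000L,
                      snp_rate = 0, indel_rate = 0,
                      n_distinct_coding = 0L, n_distinct_noncoding = 0L,
                      n_antisense_pairs = 0L, n_artifact_contigs = 0L,
                      n_redundant_copies = 0L, n_antisense_gene = 0L,
                      n_small_overlap = 0L, n_intergenic = 0L, n_multi = 0L,
                      n_intron_snps = 0L, n_splice_snps = 0L,
                      n_intergenic_snps = 0L, polya_every = 0L)
  ref <- generate_reference(cfg)
  acc <- generate_accession(cfg, ref)
  for (gid in names(ref$genes)) {
    g <- ref$genes[[gid]]
    p <- wildtx:::extract_spliced_plus(g, ref$genome)
    expected <- if (g$strand == "-") wildtx:::revcomp(p) else p
    expect_identical(unname(acc$contigs[[paste0("tx_", gid)]]), expected)
  }
  expect_identical(sum(!acc$truth$variants$is_decoy), 0L)
})

test_that("pileup recount reproduces configured depth and allele frequency", {
  synth <- small_synth()
  obs <- synth$acc$pileup
  tv <- synth$acc$truth$variants
  for (i in which(!tv$is_decoy)) {
    col <- obs[obs$chrom == tv$chrom[i] & obs$pos == tv$pos[i], ]
    expect_identical(nrow(col), synth$cfg$depth)
    alt_token <- switch(tv$vtype[i], snp = tv$alt[i],
                        ins = paste0("+", substr(tv$alt[i], 2L, 1e6L)),
                        del = paste0("-", nchar(tv$ref[i]) - 1L))
    support <- sum(col$allele == alt_token)
    expect_identical(support, synth$cfg$depth - 1L)
    expect_gt(support / nrow(col), 0.70)
    expect_gte(support, 4L)
  }
})

test_that("each decoy violates exactly one calling rule", {
  synth <- small_synth()
  obs <- synth$acc$pileup
  tv <- synth$acc$truth$variants
  dec <- tv[tv$is_decoy, ]
  expect_gt(nrow(dec), 0L)
  for (i in seq_len(nrow(dec))) {
    col <- obs[obs$chrom == dec$chrom[i] & obs$pos == dec$pos[i], ]
    support <- sum(col$allele == dec$alt[i])
    af <- support / nrow(col)
    pass_support <- support >= 4L
    pass_af <- af > 0.70
    expect_identical(pass_support + pass_af, 1L)
    if (dec$decoy_reason[i] == "af_boundary") {
      expect_identical(af, 0.70)
      expect_true(pass_support)
    } else {
      expect_identical(support, 3L)
      expect_true(pass_af)
    }
  }
})

test_that("distinct contigs share no 31-mer with the genome and stay unmapped", {
  synth <- small_synth()
  idx <- build_genome_index(synth$ref$genome)
  for (id in synth$acc$truth$distinct$contig_id) {
    expect_false(wildtx:::has_genome_kmer(synth$acc$contigs[[id]], idx, 31L))
  }
  aln <- align_transcripts(synth$acc$contigs[synth$acc$truth$distinct$contig_id],
                           synth$ref$genome, index = idx)
  expect_length(aln, 0L)
})

test_that("antisense truth follows the configured geometries and pairings", {
  cfg <- small_config()
  synth <- small_synth()
  at <- synth$acc$truth$antisense
  expect_identical(nrow(at), cfg$n_antisense_pairs)
  expect_true(all(at$geometry %in% c("head_to_head", "tail_to_tail",
                                     "contained")))
  # planted members really do overlap in reverse orientation by > 50 bp
  for (i in seq_len(nrow(at))) {
    ov <- wildtx:::local_overlap(
      synth$acc$contigs[[at$contig_a[i]]],
      wildtx:::revcomp(synth$acc$contigs[[at$contig_b[i]]]))
    expect_gt(ov$columns, 50L)
    expect_gte(ov$identity, 0.97)
  }
})

test_that("infeasible packing and out-of-domain rates are rejected", {
  expect_error(synth_config(snp_rate = 0.03), "97%")
  expect_error(synth_config(depth = 3L), "depth")
  cfg <- small_config()
  cfg$chrom_len <- 15000L
  expect_error(generate_reference(cfg), "increase chrom_len")
})
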