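mk_obs <- function(read_ids, alleles, chrom = "c1", pos = 100L, ref = "A") {
  data.frame(chrom = chrom, pos = pos, ref = ref, read_id = read_ids,
             allele = alleles, stringsAsFactors = FALSE)
}

test_that("read deduplication keeps one read per placement group", {
  obs <- mk_obs(c("r1", "r2", "r3", "r4"), c("G", "G", "G", "A"))
  meta <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                     chrom = "c1", start = c(90L, 90L, 90L, 90L),
                     strand = c("+", "+", "+", "-"),
                     blocks = "50", stringsAsFactors = FALSE)
  out <- deduplicate_reads(obs, meta)
  # r1/r2/r3 share a placement -> r1 kept; r4 differs by strand -> kept
  expect_setequal(out$read_id, c("r1", "r4"))

  meta2 <- transform(meta, start = c(90L, 91L, 92L, 93L))
  expect_identical(deduplicate_reads(obs, meta2), obs)

  expect_error(deduplicate_reads(obs, meta[-2L, ]), "missing read metadata.*r2")
})

test_that("caller enforces support >= 4 and allele frequency strictly > 0.70", {
  called <- call_variants(mk_obs(paste0("r", 1:10),
                                 c(rep("G", 8L), "A", "A")))
  expect_identical(nrow(called), 1L)
  expect_identical(called$alt, "G")
  expect_equal(called$af, 0.8)

  expect_identical(nrow(call_variants(mk_obs(paste0("r", 1:3), rep("G", 3L)))),
                   0L)
  # AF exactly 0.70 fails the strict inequality
  expect_identical(nrow(call_variants(mk_obs(paste0("r", 1:10),
                                             c(rep("G", 7L), rep("A", 3L))))),
                   0L)
  # tie between two non-reference alleles: no call
  expect_identical(nrow(call_variants(mk_obs(paste0("r", 1:10),
                                             c(rep("G", 5L), rep("C", 5L))))),
                   0L)
})

test_that("caller emits anchored indel alleles from pileup tokens", {
  ins <- call_variants(mk_obs(paste0("r", 1:10),
                              c(rep("+GG", 9L), "A"), ref = "A"))
  expect_identical(ins$vtype, "ins")
  expect_identical(ins$ref, "A")
  expect_identical(ins$alt, "AGG")

  del <- call_variants(mk_obs(paste0("r", 1:10),
                              c(rep("-2", 9L), "A"), ref = "ATT"))
  expect_identical(del$vtype, "del")
  expect_identical(del$ref, "ATT")
  expect_identical(del$alt, "A")
})

test_that("caller recovers exactly the planted variants; decoys are rejected", {
  synth <- small_synth()
  obs <- deduplicate_reads(synth$acc$pileup, synth$acc$reads)
  called <- call_variants(obs)
  tv <- synth$acc$truth$variants[!synth$acc$truth$variants$is_decoy, ]
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  expect_setequal(key(called), key(tv))
})

test_that("codon-level effects match hand-constructed cases", {
  ref <- tiny_gene_fixture()
  genes <- ref$genes
  genome <- ref$genome
  plus <- Filter(function(g) g$strand == "+", genes)[[1L]]
  cpos <- wildtx:::coding_positions(plus)

  snp_at <- function(g, coding_i, new_coding) {
    cp <- wildtx:::coding_positions(g)
    p <- cp[coding_i]
    ref_b <- substr(genome[[g$chrom]], p + 1L, p + 1L)
    alt_b <- if (g$strand == "-") chartr("ACGT", "TGCA", new_coding)
             else new_coding
    data.frame(chrom = g$chrom, pos = p, ref = ref_b, alt = alt_b,
               vtype = "snp", stringsAsFactors = FALSE)
  }
  # ATG -> GTG start loss
  v <- snp_at(plus, 1L, "G")
  eff <- annotate_effects(v, genes, genome)
  expect_identical(eff$effect, "start_lost")
  expect_identical(eff$region, "cds")

  # terminal stop, middle base -> C: stop lost
  n_cod <- length(cpos) %/% 3L
  v <- snp_at(plus, 3L * n_cod - 1L, "C")
  expect_identical(annotate_effects(v, genes, genome)$effect, "stop_lost")

  # 1 bp deletion mid-CDS: frameshift
  seg <- plus$cds[which.max(plus$cds[, 2L] - plus$cds[, 1L]), ]
  mid <- (seg[1L] + seg[2L]) %/% 2L
  del <- data.frame(chrom = plus$chrom, pos = mid,
                    ref = substr(genome[[plus$chrom]], mid + 1L, mid + 2L),
                    alt = substr(genome[[plus$chrom]], mid + 1L, mid + 1L),
                    vtype = "del", stringsAsFactors = FALSE)
  expect_identical(annotate_effects(del, genes, genome)$effect, "frameshift")

  # SNP on the G of a GT donor: splice disruption
  introns <- wildtx:::gene_introns(plus)
  dpos <- introns[1L, 1L]
  v <- data.frame(chrom = plus$chrom, pos = dpos,
                  ref = substr(genome[[plus$chrom]], dpos + 1L, dpos + 1L),
                  alt = "C", vtype = "snp", stringsAsFactors = FALSE)
  eff <- annotate_effects(v, genes, genome)
  expect_identical(eff$effect, "splice_disruption")
  expect_identical(eff$region, "splice_donor")
})

test_that("effect classes agree with the substitute-translate oracle", {
  ref <- tiny_gene_fixture()
  vars <- make_effect_variants(ref, n_random_snp = 120L, n_random_indel = 40L)
  got <- annotate_effects(vars, ref$genes, ref$genome)
  want <- vapply(seq_len(nrow(vars)), function(i) {
    effect_oracle(vars[i, ], ref$genes, ref$genome)$effect
  }, character(1))
  expect_identical(got$effect, want)
  expect_true(all(c("start_lost", "stop_lost", "stop_gained", "frameshift",
                    "splice_disruption", "synonymous", "nonsynonymous",
                    "inframe_indel") %in% got$effect))
})

test_that("effects are invariant under genome reverse-complement mirroring", {
  ref <- tiny_gene_fixture()
  g <- ref$genes[[1L]]
  chrom_seq <- ref$genome[[g$chrom]]
  L <- nchar(chrom_seq)
  mirror_pos <- function(p) L - 1L - p
  # mirror the genome and the gene annotation
  rc_genome <- stats::setNames(wildtx:::revcomp(chrom_seq), g$chrom)
  flip <- function(m) {
    out <- cbind(start = mirror_pos(m[, 2L] - 1L), end = mirror_pos(m[, 1L]) + 1L)
    out[order(out[, 1L]), , drop = FALSE]
  }
  g2 <- wildtx:::gene_model(g$gene_id, g$chrom,
                            if (g$strand == "+") "-" else "+",
                            mirror_pos(g$end - 1L), mirror_pos(g$start) + 1L,
                            flip(g$exons), flip(g$cds))
  ref1 <- list(genes = list(g1 = g), genome = ref$genome)
  vars <- make_effect_variants(ref1, seed = 123,
                               n_random_snp = 60L, n_random_indel = 0L)
  vars <- vars[vars$vtype == "snp", ]
  eff1 <- annotate_effects(vars, list(g), ref$genome)
  vars2 <- vars
  vars2$pos <- mirror_pos(vars$pos)
  vars2$ref <- chartr("ACGT", "TGCA", vars$ref)
  vars2$alt <- chartr("ACGT", "TGCA", vars$alt)
  eff2 <- annotate_effects(vars2, list(g2), rc_genome)
  expect_identical(eff1$effect, eff2$effect)
})

test_that("NS/S ratio mirrors the count ratio and flags emptiness", {
  eff <- data.frame(effect = c(rep("nonsynonymous", 7L),
                               rep("synonymous", 10L)),
                    gene_id = "g", stringsAsFactors = FALSE)
  r <- ns_ratio(eff)
  expect_equal(r$ratio, 0.7)
  expect_true(r$defined)
  r2 <- ns_ratio(data.frame(effect = rep("nonsynonymous", 5L),
                            gene_id = "g", stringsAsFactors = FALSE))
  expect_false(r2$defined)
  expect_true(is.na(r2$ratio))
  r3 <- ns_ratio(eff[0, ])
  expect_false(r3$defined)
})
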