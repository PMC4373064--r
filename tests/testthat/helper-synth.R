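# Shared fixtures, generated in code and memoised for the test run.

small_config <- function(seed = 42L) {
  synth_config(seed = seed, n_genes = 16L, chrom_len = 60000L,
               n_distinct_coding = 4L, n_distinct_noncoding = 3L,
               n_antisense_pairs = 3L, n_artifact_contigs = 2L,
               n_redundant_copies = 3L, n_antisense_gene = 2L,
               n_small_overlap = 2L, n_intergenic = 2L, n_multi = 2L,
               n_intron_snps = 8L, n_splice_snps = 6L,
               n_intergenic_snps = 8L)
}

.synth_cache <- new.env(parent = emptyenv())

# Small synthetic dataset plus qc/map stage products, computed once.
small_synth <- function() {
  if (!is.null(.synth_cache$small)) return(.synth_cache$small)
  cfg <- small_config()
  ref <- generate_reference(cfg)
  acc <- generate_accession(cfg, ref)
  trimmed <- character(0)
  for (id in names(acc$contigs)) {
    t <- suppressWarnings(trim_polya(acc$contigs[id]))
    if (!is.null(t)) trimmed[names(t)] <- unname(t)
  }
  filt <- filter_strand_artifacts(acc$counts, names(trimmed))
  kept <- trimmed[filt$kept]
  aln <- align_transcripts(kept, ref$genome)
  classes <- classify_transcripts(kept, aln, ref$genes,
                                  chroms = names(ref$genome))
  .synth_cache$small <- list(cfg = cfg, ref = ref, acc = acc,
                             trimmed = trimmed, filt = filt, kept = kept,
                             aln = aln, classes = classes)
  .synth_cache$small
}

# A tiny hand-built gene universe for effect tests: one plus-strand and one
# minus-strand two-exon gene with known CDS, on a small genome.
tiny_gene_fixture <- function(seed = 7L) {
  set.seed(seed)
  cfg <- synth_config(seed = seed, n_chroms = 2L, chrom_len = 20000L,
                      n_genes = 4L, n_antisense_pairs = 0L,
                      n_artifact_contigs = 0L, n_redundant_copies = 0L,
                      n_distinct_coding = 0L, n_distinct_noncoding = 0L,
                      n_antisense_gene = 0L, n_small_overlap = 0L,
                      n_intergenic = 0L, n_multi = 0L,
                      n_intron_snps = 0L, n_splice_snps = 0L,
                      n_intergenic_snps = 0L)
  generate_reference(cfg)
}

# Construct CDS/splice variants with guaranteed class coverage on both
# strands, plus a random bulk, for oracle-agreement tests.
make_effect_variants <- function(ref, n_random_snp = 700L,
                                 n_random_indel = 200L, seed = 99L) {
  set.seed(seed)
  genes <- ref$genes
  genome <- ref$genome
  rows <- list()
  add <- function(chrom, pos, ref_a, alt_a, vtype) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = as.integer(pos), ref = ref_a, alt = alt_a,
      vtype = vtype, stringsAsFactors = FALSE)
  }
  base_at <- function(chrom, pos) substr(genome[[chrom]], pos + 1L, pos + 1L)
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  codon_tab <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")

  for (g in genes) {
    cpos <- wildtx:::coding_positions(g)
    n_cod <- length(cpos) %/% 3L
    coding_base <- function(i) {  # 1-based coding coordinate
      b <- base_at(g$chrom, cpos[i])
      if (g$strand == "-") unname(comp[b]) else b
    }
    set_coding <- function(i, new_coding) {
      # returns genomic (pos, ref, alt) realising a coding-strand change
      gpos <- cpos[i]
      ref_g <- base_at(g$chrom, gpos)
      alt_g <- if (g$strand == "-") unname(comp[new_coding]) else new_coding
      c(pos = gpos, ref = ref_g, alt = alt_g)
    }
    # start_lost: destroy the A of ATG
    v <- set_coding(1L, sample(c("C", "G", "T"), 1L))
    add(g$chrom, v["pos"], v["ref"], v["alt"], "snp")
    # stop_lost: middle base of terminal stop -> C
    v <- set_coding(3L * n_cod - 1L, "C")
    add(g$chrom, v["pos"], v["ref"], v["alt"], "snp")
    # stop_gained + synonymous + nonsynonymous: scan interior codons
    found_gain <- FALSE; found_syn <- FALSE; found_ns <- FALSE
    for (ci in sample(seq.int(2L, n_cod - 1L))) {
      cod <- paste0(coding_base(3L * ci - 2L), coding_base(3L * ci - 1L),
                    coding_base(3L * ci))
      for (off in 0:2) {
        for (nb in setdiff(c("A", "C", "G", "T"),
                           substr(cod, off + 1L, off + 1L))) {
          new_cod <- cod
          substr(new_cod, off + 1L, off + 1L) <- nb
          cls <- if (new_cod %in% stops) "gain"
                 else if (codon_tab[[new_cod]] == codon_tab[[cod]]) "syn"
                 else "ns"
          take <- (cls == "gain" && !found_gain) ||
                  (cls == "syn" && !found_syn) || (cls == "ns" && !found_ns)
          if (take) {
            v <- set_coding(3L * (ci - 1L) + off + 1L, nb)
            add(g$chrom, v["pos"], v["ref"], v["alt"], "snp")
            if (cls == "gain") found_gain <- TRUE
            if (cls == "syn") found_syn <- TRUE
            if (cls == "ns") found_ns <- TRUE
          }
        }
      }
      if (found_gain && found_syn && found_ns) break
    }
    # splice donor and acceptor SNPs on the first intron
    introns <- wildtx:::gene_introns(g)
    if (nrow(introns) > 0L) {
      for (p in c(introns[1L, 1L], introns[1L, 2L] - 1L)) {
        b <- base_at(g$chrom, p)
        add(g$chrom, p, b, other_base(b), "snp")
      }
    }
    # frameshift (1-2 bp) and inframe (3 bp) indels in segment interiors
    seg <- g$cds[which.max(g$cds[, 2L] - g$cds[, 1L]), ]
    mid <- (seg[1L] + seg[2L]) %/% 2L
    if (seg[2L] - seg[1L] >= 60L) {
      for (d in c(1L, 3L)) {
        anchor <- mid + 4L * d
        ref_s <- substr(genome[[g$chrom]], anchor + 1L, anchor + 1L + d)
        add(g$chrom, anchor, ref_s, substr(ref_s, 1L, 1L), "del")
        ins <- paste(sample(c("A", "C", "G", "T"), d, replace = TRUE),
                     collapse = "")
        anchor2 <- mid - 4L * d
        b <- base_at(g$chrom, anchor2)
        add(g$chrom, anchor2, b, paste0(b, ins), "ins")
      }
    }
  }
  # random CDS SNPs
  gene_pick <- sample(seq_along(genes), n_random_snp, replace = TRUE)
  for (gi in gene_pick) {
    g <- genes[[gi]]
    cpos <- wildtx:::coding_positions(g)
    p <- cpos[sample(length(cpos), 1L)]
    b <- base_at(g$chrom, p)
    add(g$chrom, p, b, other_base(b), "snp")
  }
  # random interior CDS indels
  gene_pick <- sample(seq_along(genes), n_random_indel, replace = TRUE)
  for (gi in gene_pick) {
    g <- genes[[gi]]
    seg <- g$cds[sample(nrow(g$cds), 1L), ]
    if (seg[2L] - seg[1L] < 20L) next
    d <- sample(1:3, 1L)
    anchor <- sample(seq.int(seg[1L] + 4L, seg[2L] - 4L - d), 1L)
    if (stats::runif(1L) < 0.5) {
      ref_s <- substr(genome[[g$chrom]], anchor + 1L, anchor + 1L + d)
      add(g$chrom, anchor, ref_s, substr(ref_s, 1L, 1L), "del")
    } else {
      b <- base_at(g$chrom, anchor)
      ins <- paste(sample(c("A", "C", "G", "T"), d, replace = TRUE),
                   collapse = "")
      add(g$chrom, anchor, b, paste0(b, ins), "ins")
    }
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  rownames(out) <- NULL
  out
}
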