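# Synthetic reference genome + annotation. All randomness flows through the
# single RNG stream seeded from the config, so a fixed seed yields
# byte-identical files.

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

# ATG-initiated, stop-terminated coding sequence of `len` nt (multiple of 3).
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, len / 3L - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# Build one gene feature: genomic sequence plus exon/CDS intervals relative
# to the gene start. role "long_intron" forces one 650-900 bp intron (used to
# host antisense contigs).
make_gene_feature <- function(gene_id, role, cfg) {
  rng <- cfg$exons_per_gene
  n_ex <- sample(seq(rng[1L], rng[2L]), 1L)
  if (role == "long_intron" && n_ex < 2L) n_ex <- 2L
  exon_lens <- sample(80:300, n_ex, replace = TRUE)
  utr5 <- sample(15:60, 1L)
  utr3_min <- sample(15:60, 1L)
  while (sum(exon_lens) - utr5 - utr3_min < 150L) {
    exon_lens[n_ex] <- exon_lens[n_ex] + 120L
  }
  txlen <- sum(exon_lens)
  cds_len <- 3L * ((txlen - utr5 - utr3_min) %/% 3L)
  tx <- paste0(random_dna(utr5), random_cds(cds_len),
               random_dna(txlen - utr5 - cds_len))
  strand <- sample(c("+", "-"), 1L)

  intron_lens <- if (n_ex > 1L) sample(60:400, n_ex - 1L, replace = TRUE)
                 else integer(0)
  long_intron_idx <- NA_integer_
  if (role == "long_intron") {
    long_intron_idx <- sample(seq_len(n_ex - 1L), 1L)
    intron_lens[long_intron_idx] <- sample(650:900, 1L)
  }
  sense_introns <- vapply(intron_lens, function(l) {
    paste0("GT", random_dna(l - 4L), "AG")
  }, character(1))

  # genome plus-strand spliced sequence and genome-order exon lengths
  p_seq <- if (strand == "+") tx else revcomp(tx)
  g_exon_lens <- if (strand == "+") exon_lens else rev(exon_lens)
  g_introns <- if (strand == "+") sense_introns else rev(revcomp(sense_introns))
  cuts <- cumsum(g_exon_lens)
  pieces <- substring(p_seq, c(1L, cuts[-n_ex] + 1L), cuts)
  parts <- character(0)
  for (i in seq_len(n_ex)) {
    parts <- c(parts, pieces[i])
    if (i < n_ex) parts <- c(parts, g_introns[i])
  }
  gseq <- paste(parts, collapse = "")

  exon_rel <- matrix(0L, nrow = n_ex, ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  cursor <- 0L
  p_off <- integer(n_ex)  # P coordinate of each genomic exon start
  p_cursor <- 0L
  for (i in seq_len(n_ex)) {
    exon_rel[i, ] <- c(cursor, cursor + g_exon_lens[i])
    p_off[i] <- p_cursor
    cursor <- cursor + g_exon_lens[i] +
      if (i < n_ex) nchar(g_introns[i]) else 0L
    p_cursor <- p_cursor + g_exon_lens[i]
  }

  # CDS interval in transcript coords -> P coords -> genomic rel intervals
  cds_tx <- c(utr5, utr5 + cds_len)
  cds_p <- if (strand == "+") cds_tx else c(txlen - cds_tx[2L], txlen - cds_tx[1L])
  cds_rel <- NULL
  for (i in seq_len(n_ex)) {
    ps <- p_off[i]; pe <- p_off[i] + g_exon_lens[i]
    os <- max(ps, cds_p[1L]); oe <- min(pe, cds_p[2L])
    if (os < oe) {
      cds_rel <- rbind(cds_rel, c(exon_rel[i, 1L] + (os - ps),
                                  exon_rel[i, 1L] + (oe - ps)))
    }
  }
  colnames(cds_rel) <- c("start", "end")

  long_intron_rel <- if (!is.na(long_intron_idx)) {
    gi <- if (strand == "+") long_intron_idx else n_ex - long_intron_idx
    c(exon_rel[gi, 2L], exon_rel[gi + 1L, 1L])
  } else NULL

  list(type = "gene", id = gene_id, seq = gseq, strand = strand,
       exon_rel = exon_rel, cds_rel = cds_rel, role = role,
       long_intron_rel = long_intron_rel)
}

# Build one antisense (cis-NAT) locus: two overlapping member spans on
# opposite strands, with ORFs planted in private regions to realise the
# desired coding pairing.
make_nat_feature <- function(nat_id, geometry, pairing) {
  if (geometry == "contained") {
    la <- sample(780:900, 1L)
    lb <- sample(320:380, 1L)
    offs <- sample(340:(la - lb - 20L), 1L)
    locus_len <- la
    strand_a <- "+"; strand_b <- "-"
  } else {
    la <- sample(600:800, 1L)
    lb <- sample(600:800, 1L)
    ov <- sample(120:250, 1L)
    offs <- la - ov
    locus_len <- offs + lb
    if (geometry == "tail_to_tail") { strand_a <- "+"; strand_b <- "-" }
    else { strand_a <- "-"; strand_b <- "+" }
  }
  span_a <- c(0L, la)
  span_b <- c(offs, offs + lb)
  want <- switch(pairing,
                 coding_coding = c(TRUE, TRUE),
                 coding_noncoding = c(TRUE, FALSE),
                 noncoding_noncoding = c(FALSE, FALSE))
  member_seq <- function(locus, span, strand) {
    s <- substr(locus, span[1L] + 1L, span[2L])
    if (strand == "-") revcomp(s) else s
  }
  plant <- function(locus, region, strand) {
    # overwrite part of [region) with an ORF in the member's sense orientation
    max_codons <- min(135L, (region[2L] - region[1L] - 6L) %/% 3L)
    orf <- random_cds(3L * sample(101:max_codons, 1L))
    room <- region[2L] - region[1L] - nchar(orf)
    at <- region[1L] + sample(0:room, 1L)
    ins <- if (strand == "-") revcomp(orf) else orf
    paste0(substr(locus, 1L, at), ins,
           substr(locus, at + nchar(ins) + 1L, nchar(locus)))
  }
  for (try in 1:400) {
    locus <- random_dna(locus_len)
    if (want[1L]) {
      priv_a <- c(0L, offs)  # A's leading private region
      locus <- plant(locus, priv_a, strand_a)
    }
    if (want[2L]) {
      priv_b <- if (geometry == "contained") span_b else c(la, locus_len)
      locus <- plant(locus, priv_b, strand_b)
    }
    sa <- member_seq(locus, span_a, strand_a)
    sb <- member_seq(locus, span_b, strand_b)
    got <- c(longest_orf(sa) > 300L, longest_orf(sb) > 300L)
    if (identical(got, want)) {
      return(list(type = "nat", id = nat_id, seq = locus,
                  span_a = span_a, span_b = span_b,
                  strand_a = strand_a, strand_b = strand_b,
                  geometry = geometry, pairing = pairing))
    }
  }
  stop("could not realise coding pairing ", pairing, " for ", nat_id)
}

#' Generate the synthetic reference genome and annotation
#'
#' Genes carry ATG-initiated, stop-terminated CDS and GT-AG introns; cis-NAT
#' loci and a duplicated intergenic segment are written into the genome but
#' deliberately left out of the annotation. Deterministic for a fixed seed.
#'
#' @param config A [synth_config()] object.
#' @param dir Optional directory; when given, `genome.fa` and
#'   `annotation.gff3` are written there.
#' @return List with `config`, `genome` (named character vector), `genes`
#'   (gene model list) and `layout` (placement metadata consumed by
#'   [generate_accession()]).
#' @export
generate_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  roles <- rep("plain", config$n_genes)
  if (config$n_antisense_gene > 0L) {
    roles[seq_len(min(config$n_antisense_gene, config$n_genes))] <- "long_intron"
  }
  if (config$n_small_overlap > 0L) {
    i0 <- config$n_antisense_gene
    idx <- seq(i0 + 1L, min(i0 + config$n_small_overlap, config$n_genes))
    roles[idx] <- "edge"
  }
  if (sum(roles == "long_intron") < config$n_antisense_gene ||
      sum(roles == "edge") < config$n_small_overlap) {
    stop("n_genes too small for the requested antisense/small-overlap contigs")
  }
  gene_feats <- lapply(seq_len(config$n_genes), function(i) {
    make_gene_feature(sprintf("g%03d", i), roles[i], config)
  })
  geoms <- rep(c("head_to_head", "tail_to_tail", "contained"),
               length.out = config$n_antisense_pairs)
  pairs_cycle <- rep(c("coding_noncoding", "coding_coding",
                       "noncoding_noncoding"),
                     length.out = config$n_antisense_pairs)
  nat_feats <- lapply(seq_len(config$n_antisense_pairs), function(j) {
    make_nat_feature(sprintf("nat%02d", j), geoms[j], pairs_cycle[j])
  })
  dup_feats <- list()
  if (config$n_multi > 0L) {
    dup_seq <- random_dna(1000L)
    dup_feats <- list(list(type = "dup", id = "dup_src", seq = dup_seq),
                      list(type = "dup", id = "dup_copy", seq = dup_seq))
  }

  # round-robin chromosome assignment; duplicate copies pinned apart
  chrom_feats <- rep(list(list()), config$n_chroms)
  assign_feat <- function(feats, offset = 0L) {
    for (i in seq_along(feats)) {
      ch <- (i - 1L + offset) %% config$n_chroms + 1L
      chrom_feats[[ch]][[length(chrom_feats[[ch]]) + 1L]] <<- feats[[i]]
    }
  }
  assign_feat(gene_feats)
  assign_feat(nat_feats)
  if (length(dup_feats)) {
    chrom_feats[[1L]][[length(chrom_feats[[1L]]) + 1L]] <- dup_feats[[1L]]
    chrom_feats[[2L]][[length(chrom_feats[[2L]]) + 1L]] <- dup_feats[[2L]]
  }

  tail_reserve <- 6000L
  genome <- character(config$n_chroms)
  names(genome) <- sprintf("chr%d", seq_len(config$n_chroms))
  genes <- list()
  nat_rows <- list()
  dup_rows <- list()
  gene_rows <- list()
  tail_starts <- integer(config$n_chroms)
  for (ch in seq_len(config$n_chroms)) {
    feats <- chrom_feats[[ch]]
    need <- sum(vapply(feats, function(f) nchar(f$seq) + 900L, numeric(1))) +
      tail_reserve
    if (need > config$chrom_len) {
      stop("infeasible packing on chromosome ", ch,
           ": increase chrom_len to at least ", need)
    }
    pieces <- character(0)
    cursor <- 0L
    for (f in feats) {
      gap <- sample(500:900, 1L)
      pieces <- c(pieces, random_dna(gap))
      start <- cursor + gap
      pieces <- c(pieces, f$seq)
      cursor <- start + nchar(f$seq)
      chrom_name <- names(genome)[ch]
      if (f$type == "gene") {
        genes[[f$id]] <- gene_model(
          f$id, chrom_name, f$strand, start, start + nchar(f$seq),
          f$exon_rel + start, f$cds_rel + start)
        gene_rows[[f$id]] <- data.frame(
          gene_id = f$id, role = f$role,
          long_intron_start = if (is.null(f$long_intron_rel)) NA_integer_
                              else f$long_intron_rel[1L] + start,
          long_intron_end = if (is.null(f$long_intron_rel)) NA_integer_
                            else f$long_intron_rel[2L] + start,
          stringsAsFactors = FALSE)
      } else if (f$type == "nat") {
        nat_rows[[f$id]] <- data.frame(
          nat_id = f$id, chrom = chrom_name,
          a_start = start + f$span_a[1L], a_end = start + f$span_a[2L],
          b_start = start + f$span_b[1L], b_end = start + f$span_b[2L],
          strand_a = f$strand_a, strand_b = f$strand_b,
          geometry = f$geometry, pairing = f$pairing,
          stringsAsFactors = FALSE)
      } else if (f$type == "dup") {
        dup_rows[[f$id]] <- data.frame(id = f$id, chrom = chrom_name,
                                       start = start, len = nchar(f$seq),
                                       stringsAsFactors = FALSE)
      }
    }
    tail_starts[ch] <- cursor + 500L
    pieces <- c(pieces, random_dna(config$chrom_len - cursor))
    genome[ch] <- paste(pieces, collapse = "")
  }

  layout <- list(
    gene_roles = do.call(rbind, unname(gene_rows)),
    nat = if (length(nat_rows)) do.call(rbind, unname(nat_rows)) else NULL,
    dup = if (length(dup_rows)) do.call(rbind, unname(dup_rows)) else NULL,
    tail_starts = stats::setNames(tail_starts, names(genome)))

  ref <- list(config = config, genome = genome, genes = genes, layout = layout)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_gff3(genes, file.path(dir, "annotation.gff3"))
  }
  ref
}
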