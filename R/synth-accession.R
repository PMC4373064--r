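# Synthetic accession transcriptome: per-gene mature transcripts carrying
# planted SNPs/indels, distinct contigs unalignable to the genome, cis-NAT
# members, strand-flip artifacts, redundant truncated copies, helper contigs
# for every mapping category, stranded counts, pileups with decoy sites, and
# machine-readable truth tables.

BASES <- c("A", "C", "G", "T")

# Genomic position (0-based) of each base of the plus-orientation spliced
# transcript sequence P (exon concatenation in genome order).
gene_pmap <- function(gene) {
  unlist(lapply(seq_len(nrow(gene$exons)), function(i) {
    seq.int(gene$exons[i, 1L], gene$exons[i, 2L] - 1L)
  }))
}

extract_spliced_plus <- function(gene, genome) {
  paste(vapply(seq_len(nrow(gene$exons)), function(i) {
    substr(genome[[gene$chrom]], gene$exons[i, 1L] + 1L, gene$exons[i, 2L])
  }, character(1)), collapse = "")
}

# Plant SNPs/indels on the spliced plus-sequence of one gene. Sites are kept
# >= 40 bp apart, >= 35 bp from transcript ends and >= 40 bp from exon
# junctions. The spacing keeps every site in a single-exon interior, bounds
# the mismatch density below the 97%-identity contract, and leaves an intact
# seed-length stretch on both sides of every splice junction.
plant_gene_variants <- function(gene, genome, cfg) {
  gpos <- gene_pmap(gene)
  p_seq <- extract_spliced_plus(gene, genome)
  L <- nchar(p_seq)
  ok <- rep(TRUE, L)
  ok[seq_len(min(35L, L))] <- FALSE
  ok[seq.int(max(1L, L - 34L), L)] <- FALSE
  junctions <- cumsum(gene$exons[, 2L] - gene$exons[, 1L])
  for (b in junctions[-length(junctions)]) {
    ok[max(1L, b - 43L):min(L, b + 40L)] <- FALSE
  }
  total_rate <- cfg$snp_rate + cfg$indel_rate
  n_mut <- if (total_rate > 0) stats::rbinom(1L, L, total_rate) else 0L
  chosen <- integer(0)
  for (p in sample(which(ok))) {
    if (length(chosen) >= n_mut) break
    if (all(abs(chosen - p) >= 40L)) chosen <- c(chosen, p)
  }
  chosen <- sort(chosen)
  vars <- list()
  for (i in chosen) {
    is_snp <- total_rate == 0 || stats::runif(1L) < cfg$snp_rate / total_rate
    if (is_snp) {
      ref <- substr(p_seq, i, i)
      alt <- sample(setdiff(BASES, ref), 1L)
      vars[[length(vars) + 1L]] <- list(p_idx = i, vtype = "snp",
                                        pos = gpos[i], ref = ref, alt = alt,
                                        dlen = 0L, ins = "")
    } else {
      d <- sample(1:3, 1L)
      if (stats::runif(1L) < 0.5) {
        ins <- random_dna(d)
        anchor <- substr(p_seq, i, i)
        vars[[length(vars) + 1L]] <- list(p_idx = i, vtype = "ins",
                                          pos = gpos[i], ref = anchor,
                                          alt = paste0(anchor, ins),
                                          dlen = 0L, ins = ins)
      } else {
        ref <- substr(p_seq, i, i + d)
        vars[[length(vars) + 1L]] <- list(p_idx = i, vtype = "del",
                                          pos = gpos[i], ref = ref,
                                          alt = substr(ref, 1L, 1L),
                                          dlen = d, ins = "")
      }
    }
  }
  # apply right-to-left so earlier coordinates stay valid
  for (v in rev(vars)) {
    i <- v$p_idx
    if (v$vtype == "snp") {
      substr(p_seq, i, i) <- v$alt
    } else if (v$vtype == "ins") {
      p_seq <- paste0(substr(p_seq, 1L, i), v$ins,
                      substr(p_seq, i + 1L, nchar(p_seq)))
    } else {
      p_seq <- paste0(substr(p_seq, 1L, i),
                      substr(p_seq, i + v$dlen + 1L, nchar(p_seq)))
    }
  }
  variants <- if (length(vars)) {
    data.frame(chrom = gene$chrom,
               pos = vapply(vars, `[[`, integer(1), "pos"),
               ref = vapply(vars, `[[`, character(1), "ref"),
               alt = vapply(vars, `[[`, character(1), "alt"),
               vtype = vapply(vars, `[[`, character(1), "vtype"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), vtype = character(0))
  }
  list(tx_plus = p_seq, variants = variants)
}

has_genome_kmer <- function(seq, index, k) {
  km <- seq_kmers(seq, k)
  nrow(index[unique(km$kmer), on = "kmer", nomatch = NULL]) > 0L
}

#' Generate the synthetic accession transcriptome, pileups and truth tables
#'
#' See [synth_config()] for what is planted. Ground-truth variant effects are
#' computed with the substitute-and-translate oracle ([effect_oracle()]), not
#' with the annotator under test.
#'
#' @param config A [synth_config()] object (the one used for the reference).
#' @param ref Output of [generate_reference()].
#' @param dir Optional directory; when given, `transcripts.fa`, `counts.tsv`,
#'   `pileup.tsv`, `reads.tsv`, `go_map.tsv` and the `truth_*.tsv` tables are
#'   written there.
#' @return List with `contigs` (named character vector), `counts`, `pileup`
#'   (observation data.frame), `reads`, `go_map`, and `truth` (list of truth
#'   tables: `variants`, `distinct`, `antisense`, `artifacts`, `clusters`,
#'   `mapping`).
#' @export
generate_accession <- function(config, ref, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  genome <- ref$genome
  genes <- ref$genes
  layout <- ref$layout
  index <- build_genome_index(genome)
  k <- attr(index, "k")

  # --- gene transcripts with planted variants ------------------------------
  contigs <- character(0)
  tx_variants <- list()
  tx_seqs <- character(0)  # untailed transcripts, for copies/artifacts
  for (gid in names(genes)) {
    g <- genes[[gid]]
    planted <- plant_gene_variants(g, genome, config)
    tx <- if (g$strand == "+") planted$tx_plus else revcomp(planted$tx_plus)
    tx_seqs[paste0("tx_", gid)] <- tx
    tx_variants[[gid]] <- planted$variants
    contigs[paste0("tx_", gid)] <- tx
  }
  # polyA tails on every polya_every-th gene transcript
  if (config$polya_every > 0L) {
    tailed <- names(genes)[seq_along(genes) %% config$polya_every == 0L]
    for (gid in tailed) {
      id <- paste0("tx_", gid)
      contigs[id] <- paste0(contigs[id], strrep("A", 15L))
    }
  }

  plain_genes <- layout$gene_roles$gene_id[layout$gene_roles$role == "plain"]
  if (length(plain_genes) < 1L + config$n_artifact_contigs) {
    stop("not enough plain genes for artifact planting")
  }
  boundary_contig <- paste0("tx_", plain_genes[1L])

  # --- redundant truncated copies -----------------------------------------
  dup_sources <- utils::head(plain_genes, config$n_redundant_copies)
  cluster_rep <- stats::setNames(names(tx_seqs), names(tx_seqs))
  for (j in seq_along(dup_sources)) {
    src <- paste0("tx_", dup_sources[j])
    s <- tx_seqs[[src]]
    len <- max(150L, floor(0.7 * nchar(s)))
    copy <- if (j %% 2L == 0L) substr(s, 1L, len)
            else substr(s, nchar(s) - len + 1L, nchar(s))
    id <- paste0(src, "_dup")
    contigs[id] <- copy
    cluster_rep[id] <- src
  }

  # --- strand-flip artifacts ----------------------------------------------
  art_sources <- plain_genes[seq.int(2L, 1L + config$n_artifact_contigs)]
  artifact_ids <- character(0)
  for (gid in art_sources) {
    id <- paste0("tx_", gid, "_art")
    contigs[id] <- revcomp(contigs[[paste0("tx_", gid)]])
    artifact_ids <- c(artifact_ids, id)
  }

  # --- distinct contigs (31-mer screened against the genome) ---------------
  distinct_ids <- character(0)
  distinct_labels <- character(0)
  for (i in seq_len(config$n_distinct_coding)) {
    for (try in 1:200) {
      s <- paste0(random_dna(40L), random_cds(3L * sample(110:150, 1L)),
                  random_dna(sample(80:150, 1L)))
      if (!has_genome_kmer(s, index, k) && longest_orf(s) > 300L) break
    }
    id <- sprintf("distinct_c%02d", i)
    contigs[id] <- s
    distinct_ids <- c(distinct_ids, id)
    distinct_labels <- c(distinct_labels, "coding")
  }
  for (i in seq_len(config$n_distinct_noncoding)) {
    for (try in 1:500) {
      s <- random_dna(sample(450:650, 1L))
      if (!has_genome_kmer(s, index, k) && longest_orf(s) < 150L) break
    }
    if (longest_orf(s) >= 150L) stop("failed to draw a noncoding distinct contig")
    id <- sprintf("distinct_n%02d", i)
    contigs[id] <- s
    distinct_ids <- c(distinct_ids, id)
    distinct_labels <- c(distinct_labels, "noncoding")
  }

  # --- cis-NAT members -----------------------------------------------------
  nat_truth <- NULL
  if (!is.null(layout$nat)) {
    for (r in seq_len(nrow(layout$nat))) {
      nt <- layout$nat[r, ]
      sub_a <- substr(genome[[nt$chrom]], nt$a_start + 1L, nt$a_end)
      sub_b <- substr(genome[[nt$chrom]], nt$b_start + 1L, nt$b_end)
      ida <- paste0(nt$nat_id, "a")
      idb <- paste0(nt$nat_id, "b")
      contigs[ida] <- if (nt$strand_a == "-") revcomp(sub_a) else sub_a
      contigs[idb] <- if (nt$strand_b == "-") revcomp(sub_b) else sub_b
      nat_truth <- rbind(nat_truth, data.frame(
        contig_a = ida, contig_b = idb, geometry = nt$geometry,
        pairing = nt$pairing, stringsAsFactors = FALSE))
    }
  }

  # --- antisense-to-gene contigs (inside long introns) ---------------------
  anti_ids <- character(0)
  hosts <- layout$gene_roles[layout$gene_roles$role == "long_intron", ,
                             drop = FALSE]
  for (i in seq_len(min(config$n_antisense_gene, nrow(hosts)))) {
    h <- hosts[i, ]
    g <- genes[[h$gene_id]]
    lo <- h$long_intron_start + 10L
    hi <- h$long_intron_end - 10L
    len <- min(420L, hi - lo - 20L)
    s0 <- lo + sample(0:(hi - lo - len), 1L)
    sub <- substr(genome[[g$chrom]], s0 + 1L, s0 + len)
    id <- sprintf("anti%02d", i)
    contigs[id] <- if (g$strand == "+") revcomp(sub) else sub
    anti_ids <- c(anti_ids, id)
  }

  # --- small-overlap contigs (straddling a gene end, gene orientation) -----
  small_ids <- character(0)
  edges <- layout$gene_roles[layout$gene_roles$role == "edge", , drop = FALSE]
  for (i in seq_len(min(config$n_small_overlap, nrow(edges)))) {
    g <- genes[[edges$gene_id[i]]]
    sub <- substr(genome[[g$chrom]], g$end - 80L + 1L, g$end + 320L)
    id <- sprintf("small%02d", i)
    contigs[id] <- if (g$strand == "-") revcomp(sub) else sub
    small_ids <- c(small_ids, id)
  }

  # --- tail-region allocator for intergenic material -----------------------
  next_free <- layout$tail_starts
  allocate <- function(chrom, len) {
    start <- next_free[[chrom]]
    if (start + len > config$chrom_len - 50L) {
      stop("tail region exhausted on ", chrom, "; increase chrom_len")
    }
    next_free[[chrom]] <<- start + len
    start
  }
  chrom_names <- names(genome)
  intg_ids <- character(0)
  for (i in seq_len(config$n_intergenic)) {
    s0 <- allocate(chrom_names[1L], 500L)
    id <- sprintf("intg%02d", i)
    contigs[id] <- substr(genome[[chrom_names[1L]]], s0 + 1L, s0 + 400L)
    intg_ids <- c(intg_ids, id)
  }

  # --- duplicated-locus multi-mappers --------------------------------------
  multi_ids <- character(0)
  if (config$n_multi > 0L && !is.null(layout$dup)) {
    src <- layout$dup[layout$dup$id == "dup_src", ]
    windows <- list(c(100L, 450L), c(550L, 950L))
    for (i in seq_len(min(config$n_multi, length(windows)))) {
      w <- windows[[i]]
      id <- sprintf("multi%02d", i)
      contigs[id] <- substr(genome[[src$chrom]], src$start + w[1L] + 1L,
                            src$start + w[2L])
      multi_ids <- c(multi_ids, id)
    }
  }

  # --- extra genomic variants: splice, intron, intergenic ------------------
  used_pos <- paste(character(0), integer(0))
  pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  extra_vars <- list()
  multi_exon <- Filter(function(g) nrow(g$exons) > 1L, genes)
  if (config$n_splice_snps > 0L && length(multi_exon) > 0L) {
    gi <- 0L
    planted <- 0L
    while (planted < config$n_splice_snps) {
      gi <- gi + 1L
      g <- multi_exon[[(gi - 1L) %% length(multi_exon) + 1L]]
      introns <- gene_introns(g)
      intr <- introns[(gi - 1L) %/% length(multi_exon) %% nrow(introns) + 1L, ]
      pos <- if (planted %% 2L == 0L) intr[1L] + sample(0:1, 1L)
             else intr[2L] - 1L - sample(0:1, 1L)
      if (pos_key(g$chrom, pos) %in% used_pos) next
      ref <- substr(genome[[g$chrom]], pos + 1L, pos + 1L)
      extra_vars[[length(extra_vars) + 1L]] <- data.frame(
        chrom = g$chrom, pos = as.integer(pos), ref = ref,
        alt = sample(setdiff(BASES, ref), 1L), vtype = "snp",
        stringsAsFactors = FALSE)
      used_pos <- c(used_pos, pos_key(g$chrom, pos))
      planted <- planted + 1L
      if (gi > 100L * config$n_splice_snps) stop("splice-site planting stalled")
    }
  }
  with_introns <- Filter(function(g) nrow(gene_introns(g)) > 0L, genes)
  li <- layout$gene_roles
  long_introns <- li[!is.na(li$long_intron_start), , drop = FALSE]
  planted <- 0L
  guard <- 0L
  while (planted < config$n_intron_snps && length(with_introns) > 0L) {
    guard <- guard + 1L
    if (guard > 100L * config$n_intron_snps) stop("intron planting stalled")
    g <- with_introns[[sample(length(with_introns), 1L)]]
    introns <- gene_introns(g)
    intr <- introns[sample(nrow(introns), 1L), , drop = FALSE]
    if (intr[1L, 2L] - intr[1L, 1L] < 12L) next
    pos <- sample(seq.int(intr[1L, 1L] + 4L, intr[1L, 2L] - 5L), 1L)
    host <- long_introns[long_introns$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(host) && pos >= host$long_intron_start[1L] &&
        pos < host$long_intron_end[1L]) next  # keep antisense hosts pristine
    if (pos_key(g$chrom, pos) %in% used_pos) next
    ref <- substr(genome[[g$chrom]], pos + 1L, pos + 1L)
    extra_vars[[length(extra_vars) + 1L]] <- data.frame(
      chrom = g$chrom, pos = as.integer(pos), ref = ref,
      alt = sample(setdiff(BASES, ref), 1L), vtype = "snp",
      stringsAsFactors = FALSE)
    used_pos <- c(used_pos, pos_key(g$chrom, pos))
    planted <- planted + 1L
  }
  last_chrom <- chrom_names[length(chrom_names)]
  for (i in seq_len(config$n_intergenic_snps)) {
    s0 <- allocate(last_chrom, 13L)
    pos <- s0 + 5L
    ref <- substr(genome[[last_chrom]], pos + 1L, pos + 1L)
    extra_vars[[length(extra_vars) + 1L]] <- data.frame(
      chrom = last_chrom, pos = as.integer(pos), ref = ref,
      alt = sample(setdiff(BASES, ref), 1L), vtype = "snp",
      stringsAsFactors = FALSE)
  }

  true_variants <- rbind(
    do.call(rbind, unname(tx_variants)),
    do.call(rbind, extra_vars))
  true_variants <- true_variants[order(true_variants$chrom,
                                       true_variants$pos), , drop = FALSE]
  rownames(true_variants) <- NULL

  # ground-truth effects from the independent substitute-translate oracle
  eff <- lapply(seq_len(nrow(true_variants)), function(i) {
    effect_oracle(true_variants[i, ], genes, genome)
  })
  true_variants$region <- vapply(eff, `[[`, character(1), "region")
  true_variants$effect <- vapply(eff, `[[`, character(1), "effect")
  true_variants$gene_id <- vapply(eff, function(x) {
    if (is.null(x$gene_id)) NA_character_ else x$gene_id
  }, character(1))
  true_variants$is_decoy <- rep(FALSE, nrow(true_variants))
  true_variants$decoy_reason <- rep(NA_character_, nrow(true_variants))

  # --- decoy sites pinning the calling-rule boundaries ---------------------
  n_decoys <- round(config$decoy_fraction * nrow(true_variants))
  decoys <- list()
  for (i in seq_len(n_decoys)) {
    s0 <- allocate(last_chrom, 13L)
    pos <- s0 + 5L
    ref <- substr(genome[[last_chrom]], pos + 1L, pos + 1L)
    decoys[[i]] <- data.frame(
      chrom = last_chrom, pos = as.integer(pos), ref = ref,
      alt = sample(setdiff(BASES, ref), 1L), vtype = "snp",
      region = "intergenic", effect = "noncoding", gene_id = NA_character_,
      is_decoy = TRUE,
      decoy_reason = if (i %% 2L == 1L) "af_boundary" else "support_boundary",
      stringsAsFactors = FALSE)
  }
  truth_variants <- rbind(true_variants, do.call(rbind, decoys))
  truth_variants <- truth_variants[order(truth_variants$chrom,
                                         truth_variants$pos), , drop = FALSE]
  rownames(truth_variants) <- NULL

  # --- pileups and read metadata ------------------------------------------
  obs_rows <- list()
  read_rows <- list()
  emit_column <- function(chrom, pos, ref_field, alt_token, support, depth) {
    alleles <- c(rep(alt_token, support),
                 rep(substr(ref_field, 1L, 1L), depth - support))
    ids <- sprintf("rd_%s_%07d_%02d", chrom, pos, seq_len(depth))
    obs_rows[[length(obs_rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref_field, read_id = ids,
      allele = alleles, stringsAsFactors = FALSE)
    read_rows[[length(read_rows) + 1L]] <<- data.frame(
      read_id = ids, chrom = chrom, start = pos - seq_len(depth),
      strand = "+", blocks = as.character(40L + seq_len(depth)),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth_variants))) {
    v <- truth_variants[i, ]
    alt_token <- switch(v$vtype,
                        snp = v$alt,
                        ins = paste0("+", substr(v$alt, 2L, nchar(v$alt))),
                        del = paste0("-", nchar(v$ref) - 1L))
    ref_field <- if (v$vtype == "del") v$ref else substr(v$ref, 1L, 1L)
    if (!v$is_decoy) {
      emit_column(v$chrom, v$pos, ref_field, alt_token,
                  support = config$depth - 1L, depth = config$depth)
    } else if (v$decoy_reason == "af_boundary") {
      emit_column(v$chrom, v$pos, ref_field, alt_token, support = 7L,
                  depth = 10L)
    } else {
      emit_column(v$chrom, v$pos, ref_field, alt_token, support = 3L,
                  depth = 4L)
    }
  }
  for (i in seq_len(15L)) {  # reference-only columns: no call expected
    s0 <- allocate(last_chrom, 13L)
    pos <- s0 + 5L
    ref <- substr(genome[[last_chrom]], pos + 1L, pos + 1L)
    emit_column(last_chrom, pos, ref, ref, support = 0L, depth = 5L)
  }
  pileup <- do.call(rbind, obs_rows)
  reads <- do.call(rbind, read_rows)

  # --- stranded read counts ------------------------------------------------
  ids_all <- names(contigs)
  counts <- data.frame(contig_id = ids_all,
                       sense = sample(50:200, length(ids_all), replace = TRUE),
                       antisense = sample(0:4, length(ids_all), replace = TRUE),
                       stringsAsFactors = FALSE)
  counts$sense[counts$contig_id %in% artifact_ids] <- 3L
  counts$antisense[counts$contig_id %in% artifact_ids] <- 50L
  counts$sense[counts$contig_id == boundary_contig] <- 5L
  counts$antisense[counts$contig_id == boundary_contig] <- 50L

  # --- GO annotation map (pre-propagated, planted enrichment) --------------
  non_artifact <- setdiff(ids_all, artifact_ids)
  coding_distinct <- distinct_ids[distinct_labels == "coding"]
  go_rows <- list()
  for (id in non_artifact) {
    p_enriched <- if (id %in% coding_distinct) 0.4 else 0.05
    if (stats::runif(1L) < p_enriched) {
      go_rows[[length(go_rows) + 1L]] <-
        data.frame(element_id = id, term_id = "GO:0000001",
                   stringsAsFactors = FALSE)
    }
    for (t in 2:5) {
      if (stats::runif(1L) < 0.15) {
        go_rows[[length(go_rows) + 1L]] <-
          data.frame(element_id = id, term_id = sprintf("GO:%07d", t),
                     stringsAsFactors = FALSE)
      }
    }
  }
  go_map <- do.call(rbind, go_rows)

  # --- truth tables --------------------------------------------------------
  cat_df <- function(ids, category) {
    if (length(ids) == 0L) return(NULL)
    data.frame(contig_id = ids, category = category, stringsAsFactors = FALSE)
  }
  mapping <- rbind(
    cat_df(names(tx_seqs), "sense_gene"),
    cat_df(if (length(dup_sources)) paste0("tx_", dup_sources, "_dup"),
           "sense_gene"),
    if (!is.null(nat_truth)) cat_df(c(nat_truth$contig_a, nat_truth$contig_b),
                                    "intergenic"),
    cat_df(anti_ids, "antisense_gene"),
    cat_df(small_ids, "small_overlap"),
    cat_df(intg_ids, "intergenic"),
    cat_df(multi_ids, "multiple"),
    cat_df(distinct_ids, "unmapped"))
  mapping <- mapping[order(mapping$contig_id), , drop = FALSE]
  rownames(mapping) <- NULL

  clusters <- data.frame(contig_id = setdiff(non_artifact, names(cluster_rep)),
                         cluster_rep = setdiff(non_artifact, names(cluster_rep)),
                         stringsAsFactors = FALSE)
  clusters <- rbind(data.frame(contig_id = names(cluster_rep),
                               cluster_rep = unname(cluster_rep),
                               stringsAsFactors = FALSE),
                    clusters)
  clusters <- clusters[clusters$contig_id %in% non_artifact, , drop = FALSE]
  clusters <- clusters[order(clusters$contig_id), , drop = FALSE]
  rownames(clusters) <- NULL

  truth <- list(
    variants = truth_variants,
    distinct = data.frame(contig_id = distinct_ids,
                          coding_label = distinct_labels,
                          stringsAsFactors = FALSE),
    antisense = nat_truth,
    artifacts = data.frame(contig_id = artifact_ids, stringsAsFactors = FALSE),
    clusters = clusters,
    mapping = mapping)

  out <- list(contigs = contigs, counts = counts, pileup = pileup,
              reads = reads, go_map = go_map, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(contigs, file.path(dir, "transcripts.fa"))
    write_tsv(counts, file.path(dir, "counts.tsv"))
    if (is.null(go_map)) {
      go_map <- data.frame(element_id = character(0), term_id = character(0))
      out$go_map <- go_map
    }
    write_pileup(pileup, file.path(dir, "pileup.tsv"))
    reads_out <- reads
    reads_out$start <- reads_out$start + 1L
    write_tsv(reads_out, file.path(dir, "reads.tsv"))
    write_tsv(go_map, file.path(dir, "go_map.tsv"))
    tv <- truth$variants
    tv$pos <- tv$pos + 1L
    write_tsv(tv, file.path(dir, "truth_variants.tsv"))
    write_tsv(truth$distinct, file.path(dir, "truth_distinct.tsv"))
    if (!is.null(truth$antisense)) {
      write_tsv(truth$antisense, file.path(dir, "truth_antisense.tsv"))
    }
    write_tsv(truth$artifacts, file.path(dir, "truth_artifacts.tsv"))
    write_tsv(truth$clusters, file.path(dir, "truth_clusters.tsv"))
    write_tsv(truth$mapping, file.path(dir, "truth_mapping.tsv"))
  }
  out
}
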