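# Effect annotation of called variants against gene models. One effect per
# variant, chosen by severity: start_lost > stop_gained > stop_lost >
# frameshift > splice_disruption > nonsynonymous > synonymous > noncoding.

EFFECT_SEVERITY <- c(start_lost = 1, stop_gained = 2, stop_lost = 3,
                     frameshift = 4, splice_disruption = 5,
                     nonsynonymous = 6, synonymous = 7, inframe_indel = 7.5,
                     noncoding = 8)
REGION_SEVERITY <- c(splice_donor = 1, splice_acceptor = 1, cds = 2,
                     utr_exon = 3, intron = 4, intergenic = 5)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Genomic positions of CDS bases in transcription (coding) order.
coding_positions <- function(gene) {
  if (nrow(gene$cds) == 0L) return(integer(0))
  segs <- gene$cds[order(gene$cds[, 1L]), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    seq.int(segs[i, 1L], segs[i, 2L] - 1L)
  }))
  if (gene$strand == "-") rev(pos) else pos
}

# Splice windows (2 bp at each intron end) with donor/acceptor labels.
splice_windows <- function(gene) {
  introns <- gene_introns(gene)
  if (nrow(introns) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), side = character(0)))
  }
  lo <- data.frame(start = introns[, 1L], end = introns[, 1L] + 2L,
                   side = if (gene$strand == "+") "splice_donor"
                          else "splice_acceptor",
                   stringsAsFactors = FALSE)
  hi <- data.frame(start = introns[, 2L] - 2L, end = introns[, 2L],
                   side = if (gene$strand == "+") "splice_acceptor"
                          else "splice_donor",
                   stringsAsFactors = FALSE)
  rbind(lo, hi)
}

base_at <- function(genome, chrom, pos) substr(genome[[chrom]], pos + 1L, pos + 1L)

intersects <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# Affected genomic interval of a variant, 0-based half-open. Insertions use
# the two flanking bases: the inserted sequence is inside a feature only when
# the feature contains both.
variant_interval <- function(v) {
  if (v$vtype == "snp") c(v$pos, v$pos + 1L)
  else if (v$vtype == "del") c(v$pos + 1L, v$pos + nchar(v$ref))
  else c(v$pos, v$pos + 2L)
}

# Region and effect of one variant with respect to one gene model.
effect_for_gene <- function(v, gene, genome) {
  iv <- variant_interval(v)
  sw <- splice_windows(gene)
  for (i in seq_len(nrow(sw))) {
    if (intersects(iv[1L], iv[2L], sw$start[i], sw$end[i])) {
      return(list(region = sw$side[i], effect = "splice_disruption",
                  gene_id = gene$gene_id))
    }
  }
  in_cds <- nrow(gene$cds) > 0L && any(apply(gene$cds, 1L, function(seg) {
    intersects(iv[1L], iv[2L], seg[1L], seg[2L])
  }))
  if (in_cds) {
    if (v$vtype == "snp") {
      return(c(list(region = "cds"), snp_cds_effect(v, gene, genome),
               list(gene_id = gene$gene_id)))
    }
    len <- abs(nchar(v$ref) - nchar(v$alt))
    eff <- if (len %% 3L != 0L) "frameshift" else "inframe_indel"
    return(list(region = "cds", effect = eff, gene_id = gene$gene_id))
  }
  in_exon <- any(apply(gene$exons, 1L, function(seg) {
    intersects(iv[1L], iv[2L], seg[1L], seg[2L])
  }))
  if (in_exon) {
    return(list(region = "utr_exon", effect = "noncoding",
                gene_id = gene$gene_id))
  }
  if (intersects(iv[1L], iv[2L], gene$start, gene$end)) {
    return(list(region = "intron", effect = "noncoding",
                gene_id = gene$gene_id))
  }
  NULL
}

# Codon-level classification of a CDS SNP: rebuild the affected codon in
# coding orientation and compare amino acids.
snp_cds_effect <- function(v, gene, genome) {
  cpos <- coding_positions(gene)
  ci <- match(v$pos, cpos)
  if (is.na(ci)) return(list(effect = "noncoding"))  # CDS-adjacent edge
  ci <- ci - 1L
  codon_i <- ci %/% 3L
  codon_genomic <- cpos[(3L * codon_i + 1L):(3L * codon_i + 3L)]
  bases <- vapply(codon_genomic, function(p) base_at(genome, gene$chrom, p),
                  character(1))
  if (gene$strand == "-") bases <- unname(COMPLEMENT[bases])
  old_codon <- paste(bases, collapse = "")
  alt_coding <- if (gene$strand == "-") unname(COMPLEMENT[v$alt]) else v$alt
  bases[ci %% 3L + 1L] <- alt_coding
  new_codon <- paste(bases, collapse = "")
  n_codons <- length(cpos) %/% 3L
  if (codon_i == 0L && old_codon == "ATG" && new_codon != "ATG") {
    return(list(effect = "start_lost"))
  }
  old_stop <- old_codon %in% STOP_CODONS
  new_stop <- new_codon %in% STOP_CODONS
  if (old_stop && !new_stop) return(list(effect = "stop_lost"))
  if (!old_stop && new_stop) return(list(effect = "stop_gained"))
  old_aa <- CODON_TABLE[[old_codon]]
  new_aa <- CODON_TABLE[[new_codon]]
  list(effect = if (identical(old_aa, new_aa)) "synonymous" else "nonsynonymous")
}

#' Annotate genic location and functional effect of variants
#'
#' Assigns each variant a region (`splice_donor`/`splice_acceptor` — the 2-bp
#' canonical GT/AG intron ends — `cds`, `utr_exon`, `intron` or `intergenic`,
#' in that precedence over all overlapping genes) and a functional effect.
#' CDS substitutions are classified by rebuilding the affected codon in coding
#' orientation (`start_lost`, `stop_lost`, `stop_gained`, `nonsynonymous`,
#' `synonymous`); CDS indels are `frameshift` when their length is not a
#' multiple of 3, else `inframe_indel`; splice-window variants are
#' `splice_disruption`; everything else is `noncoding`. When several genes
#' overlap, the most severe effect is retained.
#'
#' @param variants data.frame from [call_variants()].
#' @param genes List of gene models.
#' @param genome Named character vector of chromosome sequences.
#' @return `variants` with added columns `region`, `effect`, `gene_id`.
#' @export
annotate_effects <- function(variants, genes, genome) {
  if (nrow(variants) > 0L) {
    bad <- setdiff(unique(variants$chrom), names(genome))
    if (length(bad)) stop("variant on unknown chromosome ", bad[1L])
  }
  gene_chrom <- vapply(genes, `[[`, character(1), "chrom")
  gene_start <- vapply(genes, `[[`, integer(1), "start")
  gene_end <- vapply(genes, `[[`, integer(1), "end")
  ann <- lapply(seq_len(nrow(variants)), function(i) {
    v <- as.list(variants[i, ])
    iv <- variant_interval(v)
    hit <- which(gene_chrom == v$chrom & gene_start < iv[2L] &
                   iv[1L] < gene_end)
    cands <- Filter(Negate(is.null),
                    lapply(genes[hit], effect_for_gene, v = v, genome = genome))
    if (length(cands) == 0L) {
      return(list(region = "intergenic", effect = "noncoding",
                  gene_id = NA_character_))
    }
    sev <- vapply(cands, function(x) EFFECT_SEVERITY[[x$effect]], numeric(1))
    reg <- vapply(cands, function(x) REGION_SEVERITY[[x$region]], numeric(1))
    cands[[order(sev, reg)[1L]]]
  })
  variants$region <- vapply(ann, `[[`, character(1), "region")
  variants$effect <- vapply(ann, `[[`, character(1), "effect")
  variants$gene_id <- vapply(ann, function(x) {
    if (is.null(x$gene_id)) NA_character_ else x$gene_id
  }, character(1))
  variants
}
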