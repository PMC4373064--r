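# Independent effect oracle: substitutes the allele into the genome,
# re-extracts the whole CDS under the coordinate shift the indel induces,
# translates it, and classifies the effect from the protein diff. Used to
# compute ground-truth effects at generation time and to cross-check the
# codon-arithmetic annotator; deliberately shares no code path with it.

# Apply a single variant to a chromosome sequence, returning the mutated
# sequence and a coordinate-shift function for annotation boundaries.
apply_variant_to_chrom <- function(chrom_seq, v) {
  p <- v$pos  # 0-based
  if (v$vtype == "snp") {
    substr(chrom_seq, p + 1L, p + 1L) <- v$alt
    list(seq = chrom_seq, shift_start = identity, shift_end = identity)
  } else if (v$vtype == "ins") {
    ins <- substr(v$alt, 2L, nchar(v$alt))
    len <- nchar(ins)
    seq2 <- paste0(substr(chrom_seq, 1L, p + 1L), ins,
                   substr(chrom_seq, p + 2L, nchar(chrom_seq)))
    list(seq = seq2,
         shift_start = function(c) ifelse(c >= p + 1L, c + len, c),
         shift_end = function(c) ifelse(c > p + 1L, c + len, c))
  } else {
    dlen <- nchar(v$ref) - 1L
    seq2 <- paste0(substr(chrom_seq, 1L, p + 1L),
                   substr(chrom_seq, p + 2L + dlen, nchar(chrom_seq)))
    shift <- function(c) ifelse(c >= p + 1L + dlen, c - dlen, c)
    list(seq = seq2, shift_start = shift, shift_end = shift)
  }
}

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, 3L * n)),
                                     no.init.codon = TRUE))
}

# Extract the coding sequence of a gene from a chromosome sequence using
# (possibly shifted) CDS intervals.
extract_cds_seq <- function(chrom_seq, cds, strand) {
  if (nrow(cds) == 0L) return("")
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  parts <- vapply(seq_len(nrow(cds)), function(i) {
    substr(chrom_seq, cds[i, 1L] + 1L, cds[i, 2L])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Ground-truth effect of a variant by substitute, re-extract and translate
#'
#' Applies the variant to the genome, re-extracts every overlapping gene's
#' CDS under the induced coordinate shift, translates it, and derives the
#' effect class from the protein comparison (start residue, internal and
#' terminal stops, length, residue diffs). Splice effects are recognised from
#' the 2-bp intron-end windows. The most severe per-gene call is returned.
#'
#' @param v A one-row data.frame or list with fields `chrom`, `pos`, `ref`,
#'   `alt`, `vtype`.
#' @param genes List of gene models.
#' @param genome Named character vector of chromosome sequences.
#' @return List with `region`, `effect`, `gene_id`.
#' @export
effect_oracle <- function(v, genes, genome) {
  v <- as.list(v)
  iv <- if (v$vtype == "snp") c(v$pos, v$pos + 1L)
        else if (v$vtype == "del") c(v$pos + 1L, v$pos + nchar(v$ref))
        else c(v$pos, v$pos + 2L)
  cands <- list()
  for (g in genes) {
    if (g$chrom != v$chrom) next
    if (!(g$start < iv[2L] && iv[1L] < g$end)) next
    introns <- gene_introns(g)
    splice_hit <- NULL
    for (i in seq_len(nrow(introns))) {
      five <- c(introns[i, 1L], introns[i, 1L] + 2L)
      three <- c(introns[i, 2L] - 2L, introns[i, 2L])
      if (five[1L] < iv[2L] && iv[1L] < five[2L]) {
        splice_hit <- if (g$strand == "+") "splice_donor" else "splice_acceptor"
      } else if (three[1L] < iv[2L] && iv[1L] < three[2L]) {
        splice_hit <- if (g$strand == "+") "splice_acceptor" else "splice_donor"
      }
    }
    if (!is.null(splice_hit)) {
      cands[[length(cands) + 1L]] <- list(region = splice_hit,
                                          effect = "splice_disruption",
                                          gene_id = g$gene_id)
      next
    }
    in_cds <- nrow(g$cds) > 0L &&
      any(g$cds[, 1L] < iv[2L] & iv[1L] < g$cds[, 2L])
    in_exon <- any(g$exons[, 1L] < iv[2L] & iv[1L] < g$exons[, 2L])
    if (!in_cds) {
      region <- if (in_exon) "utr_exon" else "intron"
      cands[[length(cands) + 1L]] <- list(region = region,
                                          effect = "noncoding",
                                          gene_id = g$gene_id)
      next
    }
    mut <- apply_variant_to_chrom(genome[[g$chrom]], v)
    cds2 <- cbind(start = mut$shift_start(g$cds[, 1L]),
                  end = mut$shift_end(g$cds[, 2L]))
    p0 <- oracle_translate(extract_cds_seq(genome[[g$chrom]], g$cds, g$strand))
    p1 <- oracle_translate(extract_cds_seq(mut$seq, cds2, g$strand))
    eff <- diff_proteins(p0, p1, v$vtype,
                         indel_len = abs(nchar(v$ref) - nchar(v$alt)))
    cands[[length(cands) + 1L]] <- list(region = "cds", effect = eff,
                                        gene_id = g$gene_id)
  }
  if (length(cands) == 0L) {
    return(list(region = "intergenic", effect = "noncoding",
                gene_id = NA_character_))
  }
  sev <- vapply(cands, function(x) EFFECT_SEVERITY[[x$effect]], numeric(1))
  cands[[which.min(sev)]]
}

# Classify from a reference/mutant protein pair.
diff_proteins <- function(p0, p1, vtype, indel_len) {
  if (vtype != "snp") {
    return(if (indel_len %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  a0 <- strsplit(p0, NULL)[[1]]
  a1 <- strsplit(p1, NULL)[[1]]
  if (a1[1L] != "M" && a0[1L] == "M") return("start_lost")
  internal0 <- which(a0 == "*")
  internal1 <- which(a1 == "*")
  # terminal stop expected at the last residue of the reference protein
  if (length(internal1) == 0L && length(internal0) > 0L &&
      max(internal0) == length(a0)) {
    if (length(internal0) == 1L) return("stop_lost")
  }
  new_stops <- setdiff(internal1, internal0)
  if (length(new_stops)) return("stop_gained")
  lost_stops <- setdiff(internal0, internal1)
  if (length(lost_stops)) return("stop_lost")
  if (identical(a0, a1)) "synonymous" else "nonsynonymous"
}
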