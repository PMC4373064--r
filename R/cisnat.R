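# cis-natural antisense transcript discovery: reverse-orientation sequence
# self-comparison, genome co-location confirmation, and overlap-geometry
# classification (Table-4-style taxonomy: head-to-head, tail-to-tail,
# contained) with coding pairing of the two members.

#' Find reverse-orientation sequence overlaps among contigs
#'
#' Compares contigs against the reverse complements of the other contigs
#' (seeded on shared 15-mers) and keeps pairs whose best local alignment
#' spans strictly more than `min_overlap` columns at identity at least
#' `min_identity`.
#'
#' @param contigs Named character vector (post strand-filter).
#' @param min_overlap Overlap must exceed this many columns (default 50,
#'   strict).
#' @param min_identity Minimum alignment identity (default 0.97).
#' @return data.frame with columns `contig_a`, `contig_b` (`a < b`),
#'   `seq_overlap`.
#' @export
find_antisense_overlaps <- function(contigs, min_overlap = 50L,
                                    min_identity = 0.97) {
  rc <- stats::setNames(revcomp(unname(contigs)), names(contigs))
  k <- 15L
  fwd_kmers <- lapply(names(contigs), function(id) {
    km <- unique(seq_kmers(contigs[[id]], k)$kmer)
    km <- km[!km %in% strrep(c("A", "C", "G", "T"), k)]
    if (length(km)) data.table(kmer = km, id = id) else NULL
  })
  rc_kmers <- lapply(names(contigs), function(id) {
    km <- unique(seq_kmers(rc[[id]], k)$kmer)
    km <- km[!km %in% strrep(c("A", "C", "G", "T"), k)]
    if (length(km)) data.table(kmer = km, id = id) else NULL
  })
  fk <- data.table::rbindlist(fwd_kmers)
  rk <- data.table::rbindlist(rc_kmers)
  empty <- data.frame(contig_a = character(0), contig_b = character(0),
                      seq_overlap = integer(0))
  if (nrow(fk) == 0L || nrow(rk) == 0L) return(empty)
  merged <- merge(fk, rk, by = "kmer", allow.cartesian = TRUE)
  merged <- merged[merged$id.x != merged$id.y, ]
  if (nrow(merged) == 0L) return(empty)
  pairs <- unique(data.frame(
    a = pmin(merged$id.x, merged$id.y),
    b = pmax(merged$id.x, merged$id.y), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ov <- local_overlap(contigs[[pairs$a[i]]], rc[[pairs$b[i]]])
    if (ov$columns > min_overlap && ov$identity >= min_identity) {
      data.frame(contig_a = pairs$a[i], contig_b = pairs$b[i],
                 seq_overlap = ov$columns, stringsAsFactors = FALSE)
    } else NULL
  })
  res <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(res)) return(empty)
  res[order(res$contig_a, res$contig_b), , drop = FALSE]
}

# Strand-aware genomic span and block-set key of a unique alignment.
aln_span <- function(a) {
  c(start = min(a$tstarts), end = max(a$tstarts + a$sizes))
}

aln_block_key <- function(a) {
  paste(a$chrom, paste(a$tstarts, a$tstarts + a$sizes, sep = "-",
                       collapse = ","), sep = ":")
}

#' Confirm candidate antisense pairs on the genome and classify geometry
#'
#' A candidate pair is a cis-NAT when both members have exactly one
#' qualifying genome alignment, on the same chromosome and opposite strands,
#' with intersecting genomic spans. Pairs whose two alignments share an
#' identical genomic block set are mirror-duplicate assembly artifacts (one
#' transcript assembled twice, not two overlapping transcripts) and are
#' discarded. Geometry: one span containing the other is `contained`;
#' otherwise the overlap involves the two members' 3' ends (`tail_to_tail`)
#' or 5' ends (`head_to_head`), with the 3' end of a minus-strand alignment
#' at the smaller genomic coordinate.
#'
#' @param pairs data.frame from [find_antisense_overlaps()].
#' @param alignments List of qualifying transcript alignments.
#' @param coding_calls Optional named character vector of `coding`/
#'   `noncoding` labels per contig (from [score_coding_potential()]); when
#'   supplied, each pair is labelled `coding_coding`, `coding_noncoding` or
#'   `noncoding_noncoding`.
#' @return data.frame with columns `contig_a`, `contig_b`, `seq_overlap`,
#'   `chrom`, `genomic_overlap`, `geometry`, `pairing`.
#' @export
confirm_and_classify <- function(pairs, alignments, coding_calls = NULL) {
  by_contig <- split(alignments,
                     vapply(alignments, `[[`, character(1), "contig_id"))
  empty <- data.frame(contig_a = character(0), contig_b = character(0),
                      seq_overlap = integer(0), chrom = character(0),
                      genomic_overlap = integer(0), geometry = character(0),
                      pairing = character(0))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ida <- pairs$contig_a[i]; idb <- pairs$contig_b[i]
    aa <- by_contig[[ida]]; ab <- by_contig[[idb]]
    if (length(aa) != 1L || length(ab) != 1L) {
      warning("pair (", ida, ", ", idb,
              ") dropped: member without a unique qualifying alignment")
      return(NULL)
    }
    aa <- aa[[1L]]; ab <- ab[[1L]]
    if (aa$chrom != ab$chrom || aa$strand == ab$strand) return(NULL)
    sa <- aln_span(aa); sb <- aln_span(ab)
    ov <- min(sa["end"], sb["end"]) - max(sa["start"], sb["start"])
    if (ov < 1L) return(NULL)
    if (aln_block_key(aa) == aln_block_key(ab)) return(NULL)  # mirror artifact
    a_in_b <- sa["start"] >= sb["start"] && sa["end"] <= sb["end"]
    b_in_a <- sb["start"] >= sa["start"] && sb["end"] <= sa["end"]
    if (a_in_b || b_in_a) {
      geometry <- "contained"
    } else {
      left_strand <- if (sa["start"] < sb["start"]) aa$strand else ab$strand
      geometry <- if (left_strand == "+") "tail_to_tail" else "head_to_head"
    }
    pairing <- NA_character_
    if (!is.null(coding_calls)) {
      la <- coding_calls[[ida]]; lb <- coding_calls[[idb]]
      n_coding <- sum(c(la, lb) == "coding")
      pairing <- c("noncoding_noncoding", "coding_noncoding",
                   "coding_coding")[n_coding + 1L]
    }
    data.frame(contig_a = ida, contig_b = idb,
               seq_overlap = pairs$seq_overlap[i], chrom = aa$chrom,
               genomic_overlap = as.integer(ov), geometry = geometry,
               pairing = pairing, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}
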