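#' Classify transcripts into genome-mapping categories
#'
#' Each contig is assigned exactly one category: `unmapped` (no qualifying
#' alignment), `multiple` (two or more qualifying alignments), or — for a
#' unique alignment — `intergenic`, `small_overlap`, `sense_gene` or
#' `antisense_gene` from the fraction of aligned contig bases whose genomic
#' images fall inside annotated gene spans (introns included). A fraction of
#' 0 is intergenic; a fraction in `(0, overlap_threshold)` is small_overlap;
#' at or above the threshold the category is sense or antisense according to
#' whether the alignment strand matches the best-overlapping gene's strand.
#'
#' @param contigs Named character vector of contig sequences, or a character
#'   vector of contig ids.
#' @param alignments List of qualifying transcript alignments from
#'   [align_transcripts()].
#' @param genes List of gene models from [read_gff3()].
#' @param overlap_threshold Gene-overlap fraction for the sense/antisense
#'   classes (default 0.90).
#' @param chroms Optional character vector of valid chromosome names; an
#'   alignment referencing any other chromosome is an error.
#' @return data.frame with columns `contig_id`, `category`, `best_gene`,
#'   `overlap_fraction`.
#' @export
classify_transcripts <- function(contigs, alignments, genes,
                                 overlap_threshold = 0.90, chroms = NULL) {
  ids <- if (is.null(names(contigs))) contigs else names(contigs)
  if (!is.null(chroms)) {
    bad <- setdiff(vapply(alignments, `[[`, character(1), "chrom"), chroms)
    if (length(bad)) stop("alignment references unknown chromosome ", bad[1L])
  }
  gene_chrom <- vapply(genes, `[[`, character(1), "chrom")
  by_contig <- split(alignments,
                     factor(vapply(alignments, `[[`, character(1), "contig_id"),
                            levels = ids))
  rows <- lapply(ids, function(id) {
    alns <- by_contig[[id]]
    if (length(alns) == 0L) {
      return(data.frame(contig_id = id, category = "unmapped",
                        best_gene = NA_character_, overlap_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (length(alns) >= 2L) {
      return(data.frame(contig_id = id, category = "multiple",
                        best_gene = NA_character_, overlap_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    }
    a <- alns[[1L]]
    g_here <- genes[gene_chrom == a$chrom]
    blocks <- IRanges::IRanges(start = a$tstarts + 1L,
                               end = a$tstarts + a$sizes)
    per_gene <- vapply(g_here, function(g) {
      span <- IRanges::IRanges(start = g$start + 1L, end = g$end)
      ov <- IRanges::pintersect(IRanges::findOverlapPairs(blocks, span))
      sum(IRanges::width(ov))
    }, numeric(1))
    merged <- IRanges::reduce(IRanges::IRanges(
      start = vapply(g_here, function(g) g$start + 1L, integer(1)),
      end = vapply(g_here, function(g) g$end, integer(1))))
    in_gene <- sum(IRanges::width(IRanges::pintersect(
      IRanges::findOverlapPairs(blocks, merged))))
    frac <- in_gene / a$aligned
    if (frac == 0) {
      cat_ <- "intergenic"; best <- NA_character_
    } else {
      best_i <- which(per_gene == max(per_gene))
      best <- sort(names(g_here)[best_i])[1L]
      if (frac < overlap_threshold) {
        cat_ <- "small_overlap"
      } else {
        cat_ <- if (genes[[best]]$strand == a$strand) "sense_gene"
                else "antisense_gene"
      }
    }
    data.frame(contig_id = id, category = cat_, best_gene = best,
               overlap_fraction = frac, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
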