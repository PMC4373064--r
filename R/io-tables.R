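# Plain-TSV dialects used for pipeline interchange. All files carry a header
# row; genomic positions are 1-based in files and 0-based in memory.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, colClasses = colClasses,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a pileup TSV
#'
#' One row per covered site: `chrom`, `pos` (1-based), `ref`, and a
#' semicolon-separated list of `read_id:allele` tokens. An allele is a base,
#' an insertion written `+SEQ`, or a deletion written `-N` (N bases following
#' the site deleted). At deletion sites `ref` holds the anchor base plus the
#' deleted reference bases.
#'
#' @param path Path to a pileup TSV.
#' @return A data.frame of observations with columns `chrom`, `pos` (0-based),
#'   `ref`, `read_id`, `allele`.
#' @export
read_pileup <- function(path) {
  tab <- read_tsv(path, colClasses = c("character", "integer", "character",
                                       "character"))
  stopifnot(identical(names(tab), c("chrom", "pos", "ref", "observations")))
  toks <- strsplit(tab$observations, ";", fixed = TRUE)
  nobs <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (is.null(flat)) flat <- character(0)
  sep <- regexpr(":", flat, fixed = TRUE)
  obs <- data.frame(
    chrom = rep(tab$chrom, nobs),
    pos = rep(tab$pos - 1L, nobs),
    ref = rep(tab$ref, nobs),
    read_id = substr(flat, 1L, sep - 1L),
    allele = substr(flat, sep + 1L, nchar(flat)),
    stringsAsFactors = FALSE
  )
  dup <- stats::aggregate(read_id ~ chrom + pos, obs,
                          function(x) anyDuplicated(x) > 0L)
  if (any(dup$read_id)) {
    stop("duplicate read_id within pileup column at ",
         dup$chrom[dup$read_id][1L], ":", dup$pos[dup$read_id][1L] + 1L)
  }
  obs
}

#' Write a pileup TSV
#'
#' @param obs Observation data.frame as returned by [read_pileup()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(obs, path) {
  key <- paste(obs$chrom, obs$pos, sep = "\r")
  ord <- order(obs$chrom, obs$pos, obs$read_id)
  obs <- obs[ord, , drop = FALSE]
  grp <- split(obs, factor(paste(obs$chrom, obs$pos, sep = "\r"),
                           levels = unique(paste(obs$chrom, obs$pos, sep = "\r"))))
  tab <- do.call(rbind, lapply(grp, function(g) {
    data.frame(chrom = g$chrom[1L], pos = g$pos[1L] + 1L, ref = g$ref[1L],
               observations = paste(g$read_id, g$allele, sep = ":",
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  write_tsv(tab, path)
}

#' Read stranded per-contig read counts
#'
#' @param path TSV with columns `contig_id`, `sense`, `antisense`.
#' @return data.frame with those columns.
#' @export
read_strand_counts <- function(path) {
  tab <- read_tsv(path, colClasses = c("character", "integer", "integer"))
  stopifnot(identical(names(tab), c("contig_id", "sense", "antisense")))
  tab
}

#' Read a GO annotation map
#'
#' @param path TSV with columns `element_id`, `term_id` (one association per
#'   row; annotations are expected to be pre-propagated to ancestor terms).
#' @return data.frame with those columns.
#' @export
read_go_map <- function(path) {
  tab <- read_tsv(path, colClasses = c("character", "character"))
  stopifnot(identical(names(tab), c("element_id", "term_id")))
  tab
}

#' Read per-read placement metadata
#'
#' @param path TSV with columns `read_id`, `chrom`, `start` (1-based),
#'   `strand`, `blocks` (comma-separated aligned block sizes with gaps, a
#'   CIGAR-equivalent placement key).
#' @return data.frame with `start` converted to 0-based.
#' @export
read_read_metadata <- function(path) {
  tab <- read_tsv(path, colClasses = c("character", "character", "integer",
                                       "character", "character"))
  stopifnot(identical(names(tab),
                      c("read_id", "chrom", "start", "strand", "blocks")))
  tab$start <- tab$start - 1L
  tab
}

#' Write transcript-to-genome alignments as TSV
#'
#' A PSL-inspired dialect: one row per alignment with `contig`, `chrom`,
#' `strand`, `qsize`, `matches`, `mismatches`, `block_count`, and
#' comma-separated `q_starts`, `t_starts`, `block_sizes` (0-based starts).
#' For minus-strand alignments the contig block starts are coordinates on the
#' reverse-complemented contig.
#'
#' @param alignments List of transcript alignments from [align_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  tab <- do.call(rbind, lapply(alignments, function(a) {
    data.frame(contig = a$contig_id, chrom = a$chrom, strand = a$strand,
               qsize = a$qsize, matches = a$matches, mismatches = a$mismatches,
               block_count = length(a$sizes),
               q_starts = paste(a$qstarts, collapse = ","),
               t_starts = paste(a$tstarts, collapse = ","),
               block_sizes = paste(a$sizes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(contig = character(0), chrom = character(0),
                      strand = character(0), qsize = integer(0),
                      matches = integer(0), mismatches = integer(0),
                      block_count = integer(0), q_starts = character(0),
                      t_starts = character(0), block_sizes = character(0))
  }
  write_tsv(tab, path)
}

#' Read transcript-to-genome alignments from TSV
#'
#' @param path Path to an alignment TSV written by [write_alignments_tsv()]
#'   (or converted from external PSL-style output).
#' @return List of transcript alignment objects.
#' @export
read_alignments_tsv <- function(path) {
  tab <- read_tsv(path, colClasses = c("character", "character", "character",
                                       "integer", "integer", "integer",
                                       "integer", "character", "character",
                                       "character"))
  lapply(seq_len(nrow(tab)), function(i) {
    aln <- transcript_alignment(
      contig_id = tab$contig[i], chrom = tab$chrom[i], strand = tab$strand[i],
      qsize = tab$qsize[i],
      qstarts = as.integer(strsplit(tab$q_starts[i], ",")[[1]]),
      tstarts = as.integer(strsplit(tab$t_starts[i], ",")[[1]]),
      sizes = as.integer(strsplit(tab$block_sizes[i], ",")[[1]]),
      matches = tab$matches[i], mismatches = tab$mismatches[i])
    aln
  })
}

# Construct and validate a block-structured transcript alignment.
transcript_alignment <- function(contig_id, chrom, strand, qsize,
                                 qstarts, tstarts, sizes,
                                 matches, mismatches) {
  stopifnot(length(qstarts) == length(sizes),
            length(tstarts) == length(sizes),
            strand %in% c("+", "-"))
  if (length(sizes) > 1L) {
    qe <- qstarts + sizes
    te <- tstarts + sizes
    if (any(qstarts[-1L] < qe[-length(qe)]) ||
        any(tstarts[-1L] < te[-length(te)])) {
      stop("alignment blocks for ", contig_id, " not colinear")
    }
  }
  aligned <- sum(sizes)
  structure(list(contig_id = contig_id, chrom = chrom, strand = strand,
                 qsize = as.integer(qsize), qstarts = as.integer(qstarts),
                 tstarts = as.integer(tstarts), sizes = as.integer(sizes),
                 matches = as.integer(matches),
                 mismatches = as.integer(mismatches),
                 aligned = as.integer(aligned),
                 identity = if (matches + mismatches > 0)
                   matches / (matches + mismatches) else 0,
                 coverage = aligned / qsize),
            class = "transcript_alignment")
}
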