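#' Assembly summary statistics
#'
#' Computes contig count, total assembled bases, N50, mean contig length and
#' GC content. N50 is the length of the contig at which the cumulative length
#' of contigs sorted in descending order first reaches half the assembly
#' total. GC content is `100 * (G + C) / (A + C + G + T)`; `N` bases are
#' excluded from the denominator.
#'
#' @param contigs Named character vector of contig sequences.
#' @return A list with `n_contigs`, `total_bases`, `n50`, `mean_length`
#'   (exact), and `gc_percent`.
#' @export
compute_assembly_stats <- function(contigs) {
  if (length(contigs) == 0L) stop("no contigs supplied")
  lens <- nchar(contigs)
  total <- sum(lens)
  sl <- sort(lens, decreasing = TRUE)
  n50 <- sl[which(cumsum(as.numeric(sl)) >= total / 2)[1L]]
  counts <- colSums(do.call(rbind, lapply(contigs, function(s) {
    tab <- table(factor(strsplit(s, NULL)[[1]], levels = c("A", "C", "G", "T", "N")))
    as.integer(tab)
  })))
  names(counts) <- c("A", "C", "G", "T", "N")
  acgt <- sum(counts[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) 100 * sum(counts[c("G", "C")]) / acgt else NA_real_
  list(n_contigs = length(contigs), total_bases = total, n50 = as.integer(n50),
       mean_length = total / length(contigs), gc_percent = gc)
}

#' Trim polyA tails from a contig
#'
#' Removes a trailing run of at least `min_run` A's; if none is present, a
#' leading run of T's (the antisense-written form of a tail) is removed
#' instead. At most one end is trimmed per call, the 3' end checked first.
#'
#' @param contig Single named character element (one contig).
#' @param min_run Minimum homopolymer run length to trim (default 10).
#' @return The trimmed contig (same name), or `NULL` with a warning when
#'   trimming would leave an empty sequence.
#' @export
trim_polya <- function(contig, min_run = 10L) {
  stopifnot(length(contig) == 1L)
  s <- unname(contig)
  id <- names(contig)
  tail_m <- regmatches(s, regexpr("A+$", s))
  if (length(tail_m) && nchar(tail_m) >= min_run) {
    s <- substr(s, 1L, nchar(s) - nchar(tail_m))
  } else {
    head_m <- regmatches(s, regexpr("^T+", s))
    if (length(head_m) && nchar(head_m) >= min_run) {
      s <- substr(s, nchar(head_m) + 1L, nchar(s))
    }
  }
  if (nchar(s) == 0L) {
    warning("contig ", id, " trimmed to length 0; dropped")
    return(NULL)
  }
  stats::setNames(s, id)
}

#' Filter strand-orientation assembly artifacts
#'
#' In a strand-specific library, incomplete second-strand digestion yields
#' mirror contigs written in the antisense direction. A contig is discarded
#' when its sense read count is strictly less than `ratio` times its
#' antisense read count.
#'
#' @param counts data.frame with columns `contig_id`, `sense`, `antisense`.
#' @param contig_ids Optional character vector of all contig ids under
#'   consideration; ids absent from `counts` are kept with a warning.
#' @param ratio Sense/antisense threshold (default 1/10).
#' @return List with character vectors `kept` and `discarded`.
#' @export
filter_strand_artifacts <- function(counts, contig_ids = counts$contig_id,
                                    ratio = 0.1) {
  if (any(counts$sense < 0L) || any(counts$antisense < 0L)) {
    stop("negative read counts")
  }
  missing <- setdiff(contig_ids, counts$contig_id)
  if (length(missing)) {
    warning(length(missing), " contig(s) missing from strand counts; kept: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  counts <- counts[counts$contig_id %in% contig_ids, , drop = FALSE]
  bad <- counts$contig_id[counts$sense < ratio * counts$antisense]
  list(kept = setdiff(contig_ids, bad), discarded = bad)
}
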