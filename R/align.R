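# Naive seed-chain-extend spliced aligner, sized for synthetic-scale genomes.
# Seeds are exact 31-mer matches; colinear seeds are chained per locus,
# genomic gaps >= 4 bp with no contig-side gap surplus are treated as introns,
# and block ends are extended by ungapped comparison with score-based
# retraction. Externally produced alignments can be substituted through the
# alignment TSV dialect.

#' Build a k-mer index of the genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param k Seed length (default 31).
#' @return A keyed data.table with columns `kmer`, `chrom`, `pos` (0-based).
#' @export
build_genome_index <- function(genome, k = 31L) {
  tabs <- lapply(names(genome), function(ch) {
    kt <- seq_kmers(genome[[ch]], k)
    if (nrow(kt) == 0L) return(NULL)
    kt$chrom <- ch
    kt
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  attr(idx, "k") <- as.integer(k)
  idx
}

# Number of matching characters between two equal-length strings.
count_matches <- function(a, b) {
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, NULL)[[1]] == strsplit(b, NULL)[[1]])
}

# Chain exact-match blocks (qs, ts, size) into the highest-scoring colinear
# chain; returns row indices of chained blocks in q order. Adjacent exact
# runs can overhang each other by a few bases when the first bases of an
# exon coincide with the first intron bases, so small overlaps are allowed
# here and trimmed away in extend_chain().
chain_blocks <- function(blocks, max_intron = 20000L, max_qgap = 500L,
                         max_overlap = 15L) {
  n <- nrow(blocks)
  ord <- order(blocks[, "qs"], blocks[, "ts"])
  b <- blocks[ord, , drop = FALSE]
  score <- b[, "size"]
  prev <- rep(NA_integer_, n)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in seq_len(i - 1L)) {
        qgap <- b[i, "qs"] - (b[j, "qs"] + b[j, "size"])
        tgap <- b[i, "ts"] - (b[j, "ts"] + b[j, "size"])
        if (qgap < -max_overlap || tgap < -max_overlap) next
        if (min(qgap, 0L) + b[i, "size"] <= 0L) next
        if (tgap > max_intron || qgap > max_qgap) next
        cand <- score[j] + b[i, "size"] - 2L
        if (cand > score[i]) {
          score[i] <- cand
          prev[i] <- j
        }
      }
    }
  }
  best <- which.max(score)
  chain <- integer(0)
  while (!is.na(best)) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  ord[chain]
}

# Align one oriented contig sequence against one genome locus given its seed
# blocks; returns block structure plus match/mismatch counts.
extend_chain <- function(seq, chrom_seq, blocks, min_intron = 4L) {
  qs <- blocks[, "qs"]; ts <- blocks[, "ts"]; sz <- blocks[, "size"]
  matches <- sum(sz)
  mismatches <- 0L
  out_qs <- qs[1L]; out_ts <- ts[1L]; out_sz <- sz[1L]
  if (nrow(blocks) > 1L) {
    for (i in 2:nrow(blocks)) {
      last <- length(out_sz)
      qe1 <- out_qs[last] + out_sz[last]
      te1 <- out_ts[last] + out_sz[last]
      # trim away any small overhang of this block under the previous one
      trim <- max(0L, qe1 - qs[i], te1 - ts[i])
      if (trim >= sz[i]) next
      qs[i] <- qs[i] + trim; ts[i] <- ts[i] + trim; sz[i] <- sz[i] - trim
      matches <- matches - trim
      cg <- qs[i] - qe1
      gg <- ts[i] - te1
      m <- min(cg, gg)
      if (m > 0L) {
        # attach the shared gap bases to whichever side matches better
        left_q <- substr(seq, qe1 + 1L, qe1 + m)
        left_t <- substr(chrom_seq, te1 + 1L, te1 + m)
        right_q <- substr(seq, qs[i] - m + 1L, qs[i])
        right_t <- substr(chrom_seq, ts[i] - m + 1L, ts[i])
        ml <- count_matches(left_q, left_t)
        mr <- count_matches(right_q, right_t)
        if (ml >= mr) {
          out_sz[last] <- out_sz[last] + m
          matches <- matches + ml
          mismatches <- mismatches + (m - ml)
        } else {
          qs[i] <- qs[i] - m; ts[i] <- ts[i] - m; sz[i] <- sz[i] + m
          matches <- matches + mr
          mismatches <- mismatches + (m - mr)
        }
        qe1 <- out_qs[last] + out_sz[last]
        te1 <- out_ts[last] + out_sz[last]
        cg <- qs[i] - qe1
        gg <- ts[i] - te1
      }
      if (cg == 0L && gg == 0L) {
        # gap fully consumed: same diagonal, merge
        out_sz[last] <- out_sz[last] + sz[i]
      } else {
        out_qs <- c(out_qs, qs[i]); out_ts <- c(out_ts, ts[i])
        out_sz <- c(out_sz, sz[i])
      }
    }
  }
  # ungapped end extension with +1/-3 scoring and retraction to the best point
  ext_left <- extend_ungapped(seq, chrom_seq, out_qs[1L], out_ts[1L], -1L)
  out_qs[1L] <- out_qs[1L] - ext_left$len
  out_ts[1L] <- out_ts[1L] - ext_left$len
  out_sz[1L] <- out_sz[1L] + ext_left$len
  matches <- matches + ext_left$matches
  mismatches <- mismatches + ext_left$mismatches
  last <- length(out_sz)
  ext_right <- extend_ungapped(seq, chrom_seq,
                               out_qs[last] + out_sz[last] - 1L,
                               out_ts[last] + out_sz[last] - 1L, 1L)
  out_sz[last] <- out_sz[last] + ext_right$len
  matches <- matches + ext_right$matches
  mismatches <- mismatches + ext_right$mismatches
  list(qs = out_qs, ts = out_ts, sz = out_sz,
       matches = matches, mismatches = mismatches)
}

extend_ungapped <- function(seq, chrom_seq, q0, t0, dir) {
  qn <- nchar(seq); tn <- nchar(chrom_seq)
  len <- 0L; score <- 0L; best_score <- 0L
  best <- list(len = 0L, matches = 0L, mismatches = 0L)
  matches <- 0L; mismatches <- 0L
  q <- q0 + dir; t <- t0 + dir
  while (q >= 0L && q < qn && t >= 0L && t < tn) {
    same <- substr(seq, q + 1L, q + 1L) == substr(chrom_seq, t + 1L, t + 1L)
    if (same) { matches <- matches + 1L; score <- score + 1L }
    else { mismatches <- mismatches + 1L; score <- score - 3L }
    len <- len + 1L
    if (score > best_score) {
      best_score <- score
      best <- list(len = len, matches = matches, mismatches = mismatches)
    }
    if (score < best_score - 12L) break
    q <- q + dir; t <- t + dir
  }
  best
}

# Align one oriented sequence; returns a list of alignment block structures.
align_oriented <- function(seq, genome, index, k, contig_id, strand,
                           qsize, max_locus_gap = 20000L) {
  hits <- index[seq_kmers(seq, k), on = "kmer", nomatch = NULL]
  if (nrow(hits) == 0L) return(list())
  names(hits)[names(hits) == "pos"] <- "tpos"
  names(hits)[names(hits) == "i.pos"] <- "qpos"
  out <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch]
    h <- h[order(h$tpos, h$qpos)]
    locus <- cumsum(c(1L, diff(h$tpos) > max_locus_gap))
    for (l in unique(locus)) {
      s <- h[locus == l]
      diag <- s$tpos - s$qpos
      o <- order(diag, s$qpos)
      d <- diag[o]; qp <- s$qpos[o]; tp <- s$tpos[o]
      brk <- c(TRUE, diff(d) != 0L | diff(qp) != 1L)
      run <- cumsum(brk)
      qs <- tapply(qp, run, min)
      ts <- tapply(tp, run, min)
      size <- tapply(qp, run, function(x) max(x) - min(x) + k)
      blocks <- cbind(qs = as.integer(qs), ts = as.integer(ts),
                      size = as.integer(size))
      chain <- chain_blocks(blocks)
      res <- extend_chain(seq, genome[[ch]], blocks[chain, , drop = FALSE])
      out[[length(out) + 1L]] <- transcript_alignment(
        contig_id = contig_id, chrom = ch, strand = strand, qsize = qsize,
        qstarts = res$qs, tstarts = res$ts, sizes = res$sz,
        matches = res$matches, mismatches = res$mismatches)
    }
  }
  out
}

#' Align transcripts to the reference genome
#'
#' Seeds exact 31-mer matches, chains colinear seeds per genomic locus
#' (genomic gaps of at least 4 bp beyond the contig gap are treated as
#' introns), fills small gaps and extends ends by ungapped comparison. Both
#' orientations are tried; minus-strand alignments report contig block
#' coordinates on the reverse-complemented contig. Only qualifying
#' alignments — identity at least `min_identity` and contig coverage at least
#' `min_coverage` — are returned.
#'
#' @param contigs Named character vector of transcript sequences.
#' @param genome Named character vector of chromosome sequences.
#' @param min_identity Minimum `matches / (matches + mismatches)` (default
#'   0.97).
#' @param min_coverage Minimum fraction of contig bases aligned (default
#'   0.90).
#' @param index Optional precomputed [build_genome_index()] result.
#' @return List of transcript alignment objects.
#' @export
align_transcripts <- function(contigs, genome, min_identity = 0.97,
                              min_coverage = 0.90, index = NULL) {
  if (is.null(index)) index <- build_genome_index(genome)
  k <- attr(index, "k")
  out <- list()
  for (id in names(contigs)) {
    seq <- contigs[[id]]
    alns <- c(align_oriented(seq, genome, index, k, id, "+", nchar(seq)),
              align_oriented(revcomp(seq), genome, index, k, id, "-",
                             nchar(seq)))
    keep <- Filter(function(a) {
      a$identity >= min_identity && a$coverage >= min_coverage
    }, alns)
    out <- c(out, keep)
  }
  out
}
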