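#' @importFrom Biostrings BStringSet readBStringSet writeXStringSet DNAString
#'   reverseComplement translate pairwiseAlignment nmatch GENETIC_CODE
#' @importFrom IRanges IRanges
#' @importFrom data.table data.table setkey rbindlist
#' @importFrom stats phyper runif
#' @importFrom utils read.table write.table
NULL

# Reverse complement of a plain character string (A/C/G/T/N alphabet).
revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# All k-mers of a sequence with their 0-based start positions.
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(data.table(kmer = character(0), pos = integer(0)))
  starts <- seq_len(n - k + 1L)
  data.table(kmer = substring(s, starts, starts + k - 1L), pos = starts - 1L)
}

CODON_TABLE <- Biostrings::GENETIC_CODE
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Translate an in-frame nucleotide string via codon-table lookup; trailing
# partial codon dropped. Codons containing N translate to "X".
translate_codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Longest open reading frame (ATG..stop) on the sense strand over the three
# forward frames, in nucleotides including the stop codon. An ORF running off
# the 3' end without a stop counts through the last complete codon.
longest_orf <- function(s) {
  n <- nchar(s)
  best <- 0L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    open_from <- NA_integer_
    for (i in seq_len(ncod)) {
      if (is.na(open_from) && is_start[i]) open_from <- i
      if (!is.na(open_from) && is_stop[i]) {
        best <- max(best, 3L * (i - open_from + 1L))
        open_from <- NA_integer_
      }
    }
    if (!is.na(open_from)) best <- max(best, 3L * (ncod - open_from + 1L))
  }
  best
}
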