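# Redundancy clustering of assembled contigs: single linkage over pairwise
# same-orientation local alignments, seeded on shared 15-mers so that only
# plausible pairs are aligned.

# Candidate same-orientation pairs sharing at least one k-mer.
candidate_pairs <- function(contigs, k = 15L) {
  ids <- names(contigs)
  tabs <- lapply(ids, function(id) {
    kt <- seq_kmers(contigs[[id]], k)
    if (nrow(kt) == 0L) return(NULL)
    km <- unique(kt$kmer)
    # homopolymer seeds (e.g. residual polyA) pair everything with everything
    km <- km[!km %in% strrep(c("A", "C", "G", "T"), k)]
    if (length(km) == 0L) return(NULL)
    data.table(kmer = km, id = id)
  })
  kt <- data.table::rbindlist(tabs)
  if (nrow(kt) == 0L) return(data.frame(a = character(0), b = character(0)))
  merged <- merge(kt, kt, by = "kmer", allow.cartesian = TRUE)
  pairs <- unique(merged[merged$id.x < merged$id.y, c("id.x", "id.y")])
  data.frame(a = pairs$id.x, b = pairs$id.y, stringsAsFactors = FALSE)
}

# Best local alignment statistics for a sequence pair: aligned columns and
# identity (matches / aligned columns, gap columns included).
local_overlap <- function(sa, sb) {
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  cols <- Biostrings::nchar(pa)
  list(columns = cols,
       identity = if (cols > 0) Biostrings::nmatch(pa) / cols else 0)
}

# Minimal union-find over a character id universe.
uf_new <- function(ids) stats::setNames(ids, ids)
uf_find <- function(uf, x) {
  while (uf[[x]] != x) x <- uf[[x]]
  x
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf[[rb]] <- ra
  uf
}

#' Cluster contigs by sequence redundancy
#'
#' Builds edges between contig pairs whose best same-orientation local
#' alignment spans at least `min_overlap` columns at identity at least
#' `min_identity`, and takes connected components (single linkage). The
#' representative of each cluster is its longest member; ties go to the
#' lexicographically smallest id.
#'
#' @param contigs Named character vector of contig sequences.
#' @param min_identity Minimum alignment identity (default 0.97).
#' @param min_overlap Minimum aligned columns (default 100).
#' @return List of clusters, each a list with `member_ids` (sorted character
#'   vector) and `representative`.
#' @export
cluster_transcripts <- function(contigs, min_identity = 0.97,
                                min_overlap = 100L) {
  ids <- names(contigs)
  uf <- uf_new(ids)
  cand <- candidate_pairs(contigs)
  for (i in seq_len(nrow(cand))) {
    a <- cand$a[i]; b <- cand$b[i]
    if (uf_find(uf, a) == uf_find(uf, b)) next
    ov <- local_overlap(contigs[[a]], contigs[[b]])
    if (ov$columns >= min_overlap && ov$identity >= min_identity) {
      uf <- uf_union(uf, a, b)
    }
  }
  roots <- vapply(ids, function(x) uf_find(uf, x), character(1))
  comps <- split(ids, roots)
  clusters <- lapply(unname(comps), function(members) {
    members <- sort(members)
    lens <- nchar(contigs[members])
    rep_id <- members[lens == max(lens)][1L]
    list(member_ids = members, representative = rep_id)
  })
  clusters[order(vapply(clusters, `[[`, character(1), "representative"))]
}

#' Score coding potential of a contig
#'
#' A transparent, length-based surrogate for SVM coding-potential
#' classifiers: the longest sense-strand open reading frame (ATG through
#' stop, or through the 3' end when no stop follows) is compared with a
#' reference ORF length. `score = longest_orf_len / orf_ref_len - 1`, so a
#' contig is labelled coding exactly when its longest ORF exceeds
#' `orf_ref_len`. The contig's sense orientation is trusted, as produced by a
#' strand-specific protocol.
#'
#' @param contig Single named character element.
#' @param orf_ref_len Reference ORF length in nucleotides (default 300).
#' @return List with `contig_id`, `longest_orf_len`, `score`, `label`.
#' @export
score_coding_potential <- function(contig, orf_ref_len = 300L) {
  stopifnot(length(contig) == 1L)
  orf <- longest_orf(unname(contig))
  score <- orf / orf_ref_len - 1
  list(contig_id = names(contig), longest_orf_len = orf, score = score,
       label = if (score > 0) "coding" else "noncoding")
}

#' Identify distinct genes among cluster representatives
#'
#' Distinct transcripts are cluster representatives with no qualifying
#' genome alignment (category `unmapped`); they are split into
#' protein-coding and non-coding sets by [score_coding_potential()].
#'
#' @param clusters Output of [cluster_transcripts()].
#' @param classes Mapping classes for (at least) the representatives, from
#'   [classify_transcripts()].
#' @param contigs Named character vector holding the representative sequences.
#' @param orf_ref_len Passed to [score_coding_potential()].
#' @return List with character vectors `coding` and `noncoding`, and
#'   `calls`, a data.frame of coding calls for the distinct representatives.
#' @export
identify_distinct <- function(clusters, classes, contigs, orf_ref_len = 300L) {
  reps <- vapply(clusters, `[[`, character(1), "representative")
  missing <- setdiff(reps, classes$contig_id)
  if (length(missing)) {
    stop("representative ", missing[1L], " has no mapping class")
  }
  cat_of <- stats::setNames(classes$category, classes$contig_id)
  distinct <- reps[cat_of[reps] == "unmapped"]
  calls <- lapply(distinct, function(id) {
    score_coding_potential(contigs[id], orf_ref_len = orf_ref_len)
  })
  labels <- vapply(calls, `[[`, character(1), "label")
  list(coding = sort(distinct[labels == "coding"]),
       noncoding = sort(distinct[labels == "noncoding"]),
       calls = data.frame(
         contig_id = distinct,
         longest_orf_len = vapply(calls, `[[`, numeric(1), "longest_orf_len"),
         score = vapply(calls, `[[`, numeric(1), "score"),
         label = labels, stringsAsFactors = FALSE))
}
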