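# Independent brute-force oracles used by both unit and acceptance tests.

# N50 by prefix enumeration over the descending-sorted multiset.
brute_n50 <- function(lens) {
  s <- sort(lens, decreasing = TRUE)
  for (i in seq_along(s)) if (sum(s[1:i]) >= sum(s) / 2) return(s[i])
}

# Single-linkage clustering by all-pairs local alignment plus graph
# components (igraph), sharing no code with cluster_transcripts().
brute_clusters <- function(contigs, min_identity = 0.97, min_overlap = 100L) {
  ids <- names(contigs)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  edges <- character(0)
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq.int(i + 1L, length(ids))) {
        ov <- wildtx:::local_overlap(contigs[[i]], contigs[[j]])
        if (ov$columns >= min_overlap && ov$identity >= min_identity) {
          edges <- c(edges, ids[i], ids[j])
        }
      }
    }
  }
  g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  unname(lapply(split(names(comp), comp), sort))
}

# Exact upper-tail hypergeometric by direct enumeration.
enum_phyper_upper <- function(k, K, N, n) {
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
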