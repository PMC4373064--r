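#' Term over-representation test (upper-tail hypergeometric)
#'
#' For each term annotated to at least one study element, computes the
#' probability of observing at least the seen number of study hits under
#' hypergeometric sampling from the background, and applies Bonferroni
#' correction over the number of tested terms. Annotations are expected to be
#' pre-propagated to ancestor terms by the caller.
#'
#' @param study Character vector of study element ids (e.g. distinct genes).
#' @param background Character vector of background element ids; must contain
#'   the study.
#' @param term_map data.frame with columns `element_id`, `term_id`.
#' @param alpha Corrected-P threshold for the `enriched` flag (default 0.05).
#' @param correction `"bonferroni"` (default) or `"fdr"`
#'   (Benjamini-Hochberg).
#' @return data.frame with columns `term_id`, `k` (study hits), `n` (study
#'   size), `K` (background hits), `N` (background size), `p_value`,
#'   `corrected_p`, `enriched`, sorted by `corrected_p` then `term_id`.
#' @export
test_enrichment <- function(study, background, term_map, alpha = 0.05,
                            correction = c("bonferroni", "fdr")) {
  correction <- match.arg(correction)
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0L) stop("empty study set")
  if (!all(study %in% background)) {
    stop("study contains ids absent from background: ",
         setdiff(study, background)[1L])
  }
  term_map <- term_map[term_map$element_id %in% background, , drop = FALSE]
  if (!all(term_map$element_id %in% background)) {
    stop("term map references ids outside the background")
  }
  term_map <- unique(term_map[, c("element_id", "term_id")])
  N <- length(background)
  n <- length(study)
  bg_hits <- table(term_map$term_id)
  st_hits <- table(term_map$term_id[term_map$element_id %in% study])
  terms <- names(st_hits)[st_hits >= 1L]  # only terms seen in the study
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      corrected_p = numeric(0), enriched = logical(0)))
  }
  k <- as.integer(st_hits[terms])
  K <- as.integer(bg_hits[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  m <- length(terms)
  corrected <- switch(correction,
                      bonferroni = pmin(1, p * m),
                      fdr = stats::p.adjust(p, method = "BH"))
  res <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    p_value = p, corrected_p = corrected,
                    enriched = corrected <= alpha, stringsAsFactors = FALSE)
  res <- res[order(res$corrected_p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
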