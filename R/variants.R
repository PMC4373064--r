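#' Remove PCR-duplicate reads from pileup observations
#'
#' Reads sharing an identical placement — chromosome, start, strand and block
#' structure — are PCR-amplification candidates; only the lexicographically
#' smallest read id of each placement group is retained, consistently across
#' all pileup columns.
#'
#' @param obs Pileup observation data.frame from [read_pileup()].
#' @param read_meta Read metadata data.frame from [read_read_metadata()];
#'   every read id appearing in `obs` must be present.
#' @return `obs` restricted to retained reads.
#' @export
deduplicate_reads <- function(obs, read_meta) {
  missing <- setdiff(unique(obs$read_id), read_meta$read_id)
  if (length(missing)) {
    stop("missing read metadata for read ", missing[1L])
  }
  key <- paste(read_meta$chrom, read_meta$start, read_meta$strand,
               read_meta$blocks, sep = "\r")
  keep <- unlist(lapply(split(read_meta$read_id, key), function(ids) {
    sort(ids)[1L]
  }), use.names = FALSE)
  obs[obs$read_id %in% keep, , drop = FALSE]
}

#' Call homozygous SNPs and small indels from pileup observations
#'
#' Per covered site, the most frequent non-reference allele is evaluated and
#' emitted when it is supported by at least `min_support` distinct reads and
#' its allele frequency (supporting reads over total distinct reads at the
#' site) strictly exceeds `min_af`. A tie between two non-reference alleles
#' yields no call. Observations are expected to be deduplicated and drawn
#' from uniquely mapped reads.
#'
#' Allele encodings follow the pileup dialect: a base for a substitution,
#' `+SEQ` for an insertion after the site, `-N` for a deletion of the `N`
#' following reference bases. Emitted indels are left-anchored on the site
#' base: for a deletion `ref` is the anchor plus deleted bases (taken from
#' the extended `ref` field of the pileup column) and `alt` the anchor; for
#' an insertion `ref` is the anchor and `alt` the anchor plus inserted bases.
#'
#' @param obs Pileup observation data.frame.
#' @param min_support Minimum distinct reads carrying the allele (default 4).
#' @param min_af Allele-frequency threshold, strict (default 0.70).
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `vtype`, `support`, `depth`, `af`, sorted by `(chrom, pos)`.
#' @export
call_variants <- function(obs, min_support = 4L, min_af = 0.70) {
  site_key <- paste(obs$chrom, obs$pos, sep = "\r")
  sites <- split(obs, site_key)
  rows <- lapply(sites, function(col) {
    depth <- nrow(col)
    if (depth == 0L) return(NULL)
    ref_site <- col$ref[1L]
    ref_base <- substr(ref_site, 1L, 1L)
    non_ref <- col$allele[col$allele != ref_base]
    if (length(non_ref) == 0L) return(NULL)
    tab <- sort(table(non_ref), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) return(NULL)
    allele <- names(tab)[1L]
    support <- as.integer(tab[1L])
    if (support < min_support || support / depth <= min_af) return(NULL)
    first <- substr(allele, 1L, 1L)
    if (first == "+") {
      ins <- substr(allele, 2L, nchar(allele))
      ref <- ref_base
      alt <- paste0(ref_base, ins)
      vtype <- "ins"
    } else if (first == "-") {
      dlen <- as.integer(substr(allele, 2L, nchar(allele)))
      if (nchar(ref_site) < dlen + 1L) {
        stop("deletion allele at ", col$chrom[1L], ":", col$pos[1L] + 1L,
             " longer than provided reference context")
      }
      ref <- substr(ref_site, 1L, dlen + 1L)
      alt <- ref_base
      vtype <- "del"
    } else {
      ref <- ref_base
      alt <- allele
      vtype <- "snp"
    }
    if (ref == alt) return(NULL)
    data.frame(chrom = col$chrom[1L], pos = col$pos[1L], ref = ref, alt = alt,
               vtype = vtype, support = support, depth = depth,
               af = support / depth, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), support = integer(0),
                      depth = integer(0), af = numeric(0))
  }
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Ratio of nonsynonymous to synonymous substitutions
#'
#' @param effects data.frame from [annotate_effects()].
#' @param gene_subset Optional character vector of gene ids to restrict to.
#' @return List with `ns`, `s`, `ratio` (NA when no synonymous variants) and
#'   `defined`.
#' @export
ns_ratio <- function(effects, gene_subset = NULL) {
  if (!is.null(gene_subset)) {
    effects <- effects[!is.na(effects$gene_id) &
                         effects$gene_id %in% gene_subset, , drop = FALSE]
  }
  ns <- sum(effects$effect == "nonsynonymous")
  s <- sum(effects$effect == "synonymous")
  list(ns = ns, s = s,
       ratio = if (s > 0) ns / s else NA_real_,
       defined = s > 0)
}
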