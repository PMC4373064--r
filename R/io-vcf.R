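#' Write annotated variants as VCF v4.2
#'
#' Positions are converted from the internal 0-based convention to 1-based
#' `POS`; indels are already left-anchored on the preceding reference base.
#' The region/effect annotation is written to `INFO` as
#' `EFF=<region>|<effect>|<gene_id>` together with `DP` and `AF`.
#'
#' @param variants data.frame of called variants, optionally carrying
#'   `region`, `effect`, `gene_id` columns from [annotate_effects()]. Must be
#'   sorted by `(chrom, pos)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wildtx",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Distinct read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Region|Effect|Gene\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(variants) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    stop("variants must be sorted by (chrom, pos)")
  }
  info <- sprintf("DP=%d;AF=%.3f", variants$depth,
                  variants$support / variants$depth)
  if (!is.null(variants$effect)) {
    gene <- ifelse(is.na(variants$gene_id), ".", variants$gene_id)
    info <- paste0(info, ";EFF=", variants$region, "|", variants$effect,
                   "|", gene)
  }
  body <- paste(variants$chrom, variants$pos + 1L, ".", variants$ref,
                variants$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
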