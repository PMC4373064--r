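#' Configuration for the synthetic genome/transcriptome generator
#'
#' Defaults describe the study conditions the generator emulates: a toy
#' two-chromosome reference with multi-exon GT-AG gene models, an accession
#' transcriptome diverged by planted SNPs/indels while keeping identity at or
#' above 97%, unalignable distinct contigs with and without ORFs, genuine
#' antisense pairs, strand-flip assembly artifacts, redundant truncated
#' copies, and pileups carrying every planted variant plus decoy sites at the
#' calling-rule boundaries.
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_chroms,chrom_len Number of chromosomes and their length (bp).
#' @param n_genes Number of annotated genes.
#' @param exons_per_gene Length-2 integer range of exon counts per gene.
#' @param snp_rate,indel_rate Per-bp planting probabilities on accession
#'   transcript copies. Their combined density is capped by a 40 bp minimum
#'   spacing between planted sites, which bounds mismatch density at 2.5%
#'   and so guarantees the >= 97% identity contract.
#' @param n_distinct_coding,n_distinct_noncoding Distinct (unalignable)
#'   contigs with a >= 300 nt ORF, or with all ORFs < 150 nt.
#' @param n_antisense_pairs Genuine cis-NAT pairs planted at intergenic loci
#'   (geometries cycle head-to-head, tail-to-tail, contained).
#' @param n_artifact_contigs Strand-flip mirror contigs (sense read count
#'   below 1/10 of antisense).
#' @param n_redundant_copies Truncated duplicate contigs for clustering.
#' @param depth Distinct reads per planted variant site in pileups.
#' @param decoy_fraction Fraction (of planted variants) of decoy pileup sites
#'   violating exactly one calling rule (AF exactly 0.70, or support exactly
#'   3).
#' @param n_antisense_gene,n_small_overlap,n_intergenic,n_multi Planted
#'   contigs for the remaining mapping categories: antisense-to-gene, small
#'   gene overlap, purely intergenic, and duplicated-locus multi-mappers.
#' @param n_intron_snps,n_splice_snps,n_intergenic_snps Additional genomic
#'   variants planted outside coding exons.
#' @param polya_every Every this-many-th gene transcript receives a 15 nt
#'   polyA tail.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 2L, chrom_len = 150000L,
                         n_genes = 60L, exons_per_gene = c(2L, 5L),
                         snp_rate = 0.010, indel_rate = 0.0015,
                         n_distinct_coding = 12L, n_distinct_noncoding = 8L,
                         n_antisense_pairs = 6L, n_artifact_contigs = 5L,
                         n_redundant_copies = 10L,
                         depth = 10L, decoy_fraction = 0.3,
                         n_antisense_gene = 3L, n_small_overlap = 3L,
                         n_intergenic = 3L, n_multi = 2L,
                         n_intron_snps = 30L, n_splice_snps = 12L,
                         n_intergenic_snps = 30L,
                         polya_every = 5L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              snp_rate = snp_rate, indel_rate = indel_rate,
              n_distinct_coding = as.integer(n_distinct_coding),
              n_distinct_noncoding = as.integer(n_distinct_noncoding),
              n_antisense_pairs = as.integer(n_antisense_pairs),
              n_artifact_contigs = as.integer(n_artifact_contigs),
              n_redundant_copies = as.integer(n_redundant_copies),
              depth = as.integer(depth), decoy_fraction = decoy_fraction,
              n_antisense_gene = as.integer(n_antisense_gene),
              n_small_overlap = as.integer(n_small_overlap),
              n_intergenic = as.integer(n_intergenic),
              n_multi = as.integer(n_multi),
              n_intron_snps = as.integer(n_intron_snps),
              n_splice_snps = as.integer(n_splice_snps),
              n_intergenic_snps = as.integer(n_intergenic_snps),
              polya_every = as.integer(polya_every))
  counts <- cfg[grep("^n_", names(cfg))]
  if (any(unlist(counts) < 0L)) stop("all counts must be >= 0")
  if (cfg$snp_rate < 0 || cfg$snp_rate >= 1 ||
      cfg$indel_rate < 0 || cfg$indel_rate >= 1 ||
      cfg$decoy_fraction < 0 || cfg$decoy_fraction >= 1) {
    stop("rates must lie in [0, 1)")
  }
  if (cfg$snp_rate + cfg$indel_rate > 1 / 40) {
    stop("snp_rate + indel_rate above 1/40 cannot respect the 40 bp site ",
         "spacing that guarantees transcript identity >= 97%")
  }
  if (length(cfg$exons_per_gene) != 2L ||
      cfg$exons_per_gene[1L] < 1L ||
      cfg$exons_per_gene[2L] < cfg$exons_per_gene[1L]) {
    stop("exons_per_gene must be an increasing range of positive counts")
  }
  if (cfg$depth < 5L) stop("depth must be >= 5 so planted variants can pass ",
                           "support >= 4 at AF > 0.70")
  if (cfg$n_multi > 0L && cfg$n_chroms < 2L) {
    stop("duplicated-locus contigs need n_chroms >= 2")
  }
  structure(cfg, class = "synth_config")
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys are [synth_config()] arguments.
#' @return A `synth_config` object.
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(synth_config, vals)
}
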