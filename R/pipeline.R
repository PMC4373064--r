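#' Pipeline configuration
#'
#' Collects every stage threshold. Defaults are the analysis' canonical
#' values: 97% alignment/clustering identity, 90% gene-overlap fraction,
#' 100 bp cluster overlap, 1/10 sense/antisense ratio, 4 supporting reads,
#' allele frequency above 0.70, cis-NAT overlap above 50 bp, 300 nt reference
#' ORF, corrected-P threshold 0.05.
#'
#' @param min_identity,overlap_threshold,cluster_min_overlap,strand_ratio
#'   Stage thresholds (see module functions).
#' @param min_support,min_af Variant-calling thresholds.
#' @param cisnat_min_overlap,orf_ref_len,alpha Remaining thresholds.
#' @param seed Seed forwarded to the synthetic generator in synth mode.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_identity = 0.97, overlap_threshold = 0.90,
                            cluster_min_overlap = 100L, strand_ratio = 0.1,
                            min_support = 4L, min_af = 0.70,
                            cisnat_min_overlap = 50L, orf_ref_len = 300L,
                            alpha = 0.05, seed = 1L) {
  cfg <- list(min_identity = min_identity,
              overlap_threshold = overlap_threshold,
              cluster_min_overlap = as.integer(cluster_min_overlap),
              strand_ratio = strand_ratio,
              min_support = as.integer(min_support), min_af = min_af,
              cisnat_min_overlap = as.integer(cisnat_min_overlap),
              orf_ref_len = as.integer(orf_ref_len), alpha = alpha,
              seed = as.integer(seed))
  frac <- c("min_identity", "overlap_threshold", "strand_ratio", "min_af",
            "alpha")
  for (f in frac) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$min_support < 1L || cfg$cluster_min_overlap < 1L ||
      cfg$cisnat_min_overlap < 0L || cfg$orf_ref_len < 3L) {
    stop("count thresholds out of domain")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full characterization pipeline
#'
#' Executes qc (polyA trim, assembly statistics, strand-artifact filter) ->
#' map (spliced alignment, mapping-category classification) -> distinct
#' (redundancy clustering, coding split of unmapped representatives) ->
#' variants (calling, effect annotation, NS/S) -> cisnat -> enrich, writing
#' each stage's outputs under `out_dir`. In synth mode the inputs are drawn
#' from the seeded generator and a truth-vs-called comparison is added.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param synth `NULL` for real inputs; `TRUE` for a default [synth_config()]
#'   built from `config$seed`; or a `synth_config` object.
#' @param inputs For real inputs, a named list of paths: `transcripts`,
#'   `genome`, `annotation`, `counts`, `pileup`, and optionally `reads`,
#'   `go_map`.
#' @return A report list (stage outputs, counts, and in synth mode a
#'   `truth_comparison` data.frame), invisibly.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), synth = NULL,
                         inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (!is.null(synth)) {
    if (isTRUE(synth)) synth <- synth_config(seed = config$seed)
    stage_msg("simulate", "generating synthetic reference and accession")
    ref <- generate_reference(synth, dir = file.path(out_dir, "synth"))
    acc <- generate_accession(synth, ref, dir = file.path(out_dir, "synth"))
    contigs <- acc$contigs
    genome <- ref$genome
    genes <- ref$genes
    counts <- acc$counts
    pileup <- acc$pileup
    reads <- acc$reads
    go_map <- acc$go_map
    truth <- acc$truth
  } else {
    if (is.null(inputs$annotation) || !file.exists(inputs$annotation %||% "")) {
      stop("stage map: annotation GFF3 missing")
    }
    contigs <- read_fasta(inputs$transcripts)
    genome <- read_fasta(inputs$genome)
    genes <- read_gff3(inputs$annotation, genome)
    counts <- read_strand_counts(inputs$counts)
    pileup <- read_pileup(inputs$pileup)
    reads <- if (!is.null(inputs$reads)) read_read_metadata(inputs$reads)
             else NULL
    go_map <- if (!is.null(inputs$go_map)) read_go_map(inputs$go_map)
              else NULL
  }

  # --- qc ------------------------------------------------------------------
  trimmed <- character(0)
  for (id in names(contigs)) {
    t <- trim_polya(contigs[id])
    if (!is.null(t)) trimmed[names(t)] <- unname(t)
  }
  stats <- compute_assembly_stats(trimmed)
  filt <- filter_strand_artifacts(counts, names(trimmed),
                                  ratio = config$strand_ratio)
  kept <- trimmed[filt$kept]
  stage_msg("qc", length(contigs), " contigs in, ", length(kept),
            " kept after polyA trim and strand filter")
  stats_tab <- data.frame(
    metric = c("n_contigs", "total_bases", "n50", "mean_length", "gc_percent"),
    value = c(stats$n_contigs, stats$total_bases, stats$n50,
              round(stats$mean_length), round(stats$gc_percent, 1)))
  write_tsv(stats_tab, file.path(out_dir, "assembly_stats.tsv"))
  write_fasta(kept, file.path(out_dir, "contigs_filtered.fa"))

  # --- map -----------------------------------------------------------------
  index <- build_genome_index(genome)
  alignments <- align_transcripts(kept, genome,
                                  min_identity = config$min_identity,
                                  index = index)
  classes <- classify_transcripts(kept, alignments, genes,
                                  overlap_threshold = config$overlap_threshold,
                                  chroms = names(genome))
  stage_msg("map", length(alignments), " qualifying alignments; ",
            sum(classes$category == "unmapped"), " unmapped contigs")
  write_alignments_tsv(alignments, file.path(out_dir, "alignments.tsv"))
  write_tsv(classes, file.path(out_dir, "mapping_classes.tsv"))

  # --- distinct ------------------------------------------------------------
  clusters <- cluster_transcripts(kept, min_identity = config$min_identity,
                                  min_overlap = config$cluster_min_overlap)
  distinct <- identify_distinct(clusters, classes, kept,
                                orf_ref_len = config$orf_ref_len)
  stage_msg("distinct", length(clusters), " clusters; ",
            length(distinct$coding), " distinct coding, ",
            length(distinct$noncoding), " distinct noncoding")
  memb <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(contig_id = cl$member_ids, representative = cl$representative,
               stringsAsFactors = FALSE)
  }))
  write_tsv(memb, file.path(out_dir, "clusters.tsv"))
  if (length(distinct$coding)) {
    write_fasta(kept[distinct$coding], file.path(out_dir, "distinct_coding.fa"))
  }
  if (length(distinct$noncoding)) {
    write_fasta(kept[distinct$noncoding],
                file.path(out_dir, "distinct_noncoding.fa"))
  }

  # --- variants ------------------------------------------------------------
  obs <- if (!is.null(reads)) deduplicate_reads(pileup, reads) else pileup
  variants <- call_variants(obs, min_support = config$min_support,
                            min_af = config$min_af)
  effects <- annotate_effects(variants, genes, genome)
  nss <- ns_ratio(effects)
  stage_msg("variants", nrow(variants), " variants called; NS/S = ",
            if (nss$defined) round(nss$ratio, 3) else "undefined")
  write_vcf(effects, file.path(out_dir, "variants.vcf"))
  eff_counts <- as.data.frame(table(region = effects$region,
                                    effect = effects$effect))
  eff_counts <- eff_counts[eff_counts$Freq > 0L, , drop = FALSE]
  write_tsv(eff_counts, file.path(out_dir, "effect_counts.tsv"))

  # --- cisnat --------------------------------------------------------------
  coding_calls <- vapply(names(kept), function(id) {
    score_coding_potential(kept[id], orf_ref_len = config$orf_ref_len)$label
  }, character(1))
  cands <- find_antisense_overlaps(kept,
                                   min_overlap = config$cisnat_min_overlap,
                                   min_identity = config$min_identity)
  pairs <- confirm_and_classify(cands, alignments, coding_calls)
  stage_msg("cisnat", nrow(cands), " candidate pairs, ", nrow(pairs),
            " confirmed cis-NAT pairs")
  write_tsv(pairs, file.path(out_dir, "cisnat_pairs.tsv"))

  # --- enrich --------------------------------------------------------------
  enrichment <- NULL
  if (!is.null(go_map) && length(distinct$coding)) {
    background <- vapply(clusters, `[[`, character(1), "representative")
    enrichment <- test_enrichment(distinct$coding, background, go_map,
                                  alpha = config$alpha)
    stage_msg("enrich", sum(enrichment$enriched), " of ", nrow(enrichment),
              " terms enriched at corrected P <= ", config$alpha)
    write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  }

  report <- list(config = config, assembly_stats = stats, classes = classes,
                 clusters = clusters, distinct = distinct,
                 variants = effects, ns = nss, cisnat = pairs,
                 enrichment = enrichment, kept = names(kept),
                 discarded = filt$discarded)

  if (!is.null(truth)) {
    cmp <- compare_to_truth(report, truth)
    write_tsv(cmp, file.path(out_dir, "truth_comparison.tsv"))
    report$truth_comparison <- cmp
    report$synth_data <- list(ref = ref, acc = acc)
    stage_msg("truth", sum(!cmp$agree), " discrepancies across ",
              nrow(cmp), " checks")
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truth-vs-called comparison for synth mode; one row per check.
compare_to_truth <- function(report, truth) {
  rows <- list()
  add <- function(check, expected, observed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, expected = as.character(expected),
      observed = as.character(observed),
      agree = identical(as.character(expected), as.character(observed)),
      stringsAsFactors = FALSE)
  }
  # strand filter
  add("artifacts_removed",
      paste(sort(truth$artifacts$contig_id), collapse = ","),
      paste(sort(report$discarded), collapse = ","))
  # variant calling
  tv <- truth$variants[!truth$variants$is_decoy, , drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  called <- report$variants
  add("variant_recall", nrow(tv), sum(key(tv) %in% key(called)))
  add("variant_precision", nrow(called), sum(key(called) %in% key(tv)))
  # effect agreement on called true variants
  m <- merge(called, tv, by = c("chrom", "pos", "ref", "alt"))
  add("effect_agreement", nrow(m), sum(m$effect.x == m$effect.y))
  # mapping categories
  mt <- merge(truth$mapping, report$classes, by = "contig_id")
  add("mapping_agreement", nrow(truth$mapping),
      sum(mt$category.x == mt$category.y))
  # clustering partition (representative assignment per contig)
  rep_of <- unlist(lapply(report$clusters, function(cl) {
    stats::setNames(rep(cl$representative, length(cl$member_ids)),
                    cl$member_ids)
  }))
  ct <- truth$clusters
  add("cluster_agreement", nrow(ct),
      sum(rep_of[ct$contig_id] == ct$cluster_rep, na.rm = TRUE))
  # distinct sets
  add("distinct_coding",
      paste(sort(truth$distinct$contig_id[truth$distinct$coding_label ==
                                            "coding"]), collapse = ","),
      paste(sort(report$distinct$coding), collapse = ","))
  add("distinct_noncoding",
      paste(sort(truth$distinct$contig_id[truth$distinct$coding_label ==
                                            "noncoding"]), collapse = ","),
      paste(sort(report$distinct$noncoding), collapse = ","))
  # cis-NAT pairs, geometry and pairing
  if (!is.null(truth$antisense)) {
    pkey <- function(d) paste(d$contig_a, d$contig_b, d$geometry, d$pairing)
    add("cisnat_pairs",
        paste(sort(pkey(truth$antisense)), collapse = ";"),
        paste(sort(pkey(report$cisnat)), collapse = ";"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
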