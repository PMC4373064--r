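#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` rows linked by `Parent` attributes into a
#' list of gene models. When a gene carries several mRNAs the first one in
#' file order is retained with a warning. All coordinates are converted to the
#' package-internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param genome Named character vector of chromosome sequences, used for
#'   bounds checking.
#' @return A list of gene models. Each element is a list with fields
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open gene
#'   span), `exons` and `cds` (two-column integer matrices of 0-based
#'   half-open intervals, sorted by start; `cds` may have zero rows).
#' @export
read_gff3 <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$parent <- vapply(gr$Parent, function(p) {
    if (length(p)) p[[1L]] else NA_character_
  }, character(1))

  bad_chrom <- setdiff(unique(df$seqnames), names(genome))
  if (length(bad_chrom)) stop("GFF3 references unknown chromosome ", bad_chrom[1L])
  over <- df$end > nchar(genome)[df$seqnames]
  if (any(over)) {
    stop("feature beyond chromosome end: ", df$type[which(over)[1L]],
         " at ", df$seqnames[which(over)[1L]], ":", df$end[which(over)[1L]])
  }

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$ID
    tx <- mrnas[!is.na(mrnas$parent) & mrnas$parent == gid, , drop = FALSE]
    if (nrow(tx) == 0L) stop("gene ", gid, " has no mRNA feature")
    if (nrow(tx) > 1L) {
      warning("gene ", gid, " has ", nrow(tx), " mRNAs; keeping first (",
              tx$ID[1L], ")")
      tx <- tx[1L, , drop = FALSE]
    }
    kids <- df[!is.na(df$parent) & df$parent == tx$ID, , drop = FALSE]
    exons <- kids[kids$type == "exon", , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(exons) == 0L) stop("mRNA ", tx$ID, " has no exon features")
    exm <- cbind(start = exons$start - 1L, end = exons$end)
    exm <- exm[order(exm[, 1L]), , drop = FALSE]
    cdm <- if (nrow(cds)) {
      m <- cbind(start = cds$start - 1L, end = cds$end)
      m[order(m[, 1L]), , drop = FALSE]
    } else {
      matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    }
    models[[i]] <- gene_model(gid, g$seqnames, g$strand,
                              g$start - 1L, g$end, exm, cdm)
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

# Construct and validate a gene model (internal 0-based half-open intervals).
gene_model <- function(gene_id, chrom, strand, start, end, exons, cds) {
  stopifnot(strand %in% c("+", "-"))
  if (nrow(exons) > 1L) {
    if (any(diff(exons[, 1L]) <= 0)) stop("gene ", gene_id, ": exons not sorted")
    introns <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(introns < 4L)) {
      stop("gene ", gene_id, ": intron shorter than 4 bp (exons overlap or abut)")
    }
  }
  if (any(exons[, 1L] < start) || any(exons[, 2L] > end)) {
    stop("gene ", gene_id, ": exon outside gene span")
  }
  if (nrow(cds)) {
    cds_len <- sum(cds[, 2L] - cds[, 1L])
    if (cds_len %% 3L != 0L) {
      stop("gene ", gene_id, ": CDS length ", cds_len, " not divisible by 3")
    }
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1))
    if (!all(inside)) stop("gene ", gene_id, ": CDS segment outside exons")
  }
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       start = as.integer(start), end = as.integer(end),
       exons = exons, cds = cds)
}

# Intron intervals (0-based half-open) of a gene model, sorted by start.
gene_introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-nrow(ex), 2L], end = ex[-1L, 1L])
}

#' Write gene models to a GFF3 file
#'
#' Emits `gene`, `mRNA` (one per gene, id `<gene_id>.t1`), `exon` and `CDS`
#' rows with 1-based inclusive coordinates and CDS phase.
#'
#' @param genes List of gene models as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    tid <- paste0(g$gene_id, ".t1")
    r <- list(
      data.frame(chrom = g$chrom, start = g$start + 1L, end = g$end,
                 strand = g$strand, type = "gene", phase = ".",
                 attr = paste0("ID=", g$gene_id)),
      data.frame(chrom = g$chrom, start = g$start + 1L, end = g$end,
                 strand = g$strand, type = "mRNA", phase = ".",
                 attr = paste0("ID=", tid, ";Parent=", g$gene_id))
    )
    ex <- data.frame(chrom = g$chrom, start = g$exons[, 1L] + 1L,
                     end = g$exons[, 2L], strand = g$strand, type = "exon",
                     phase = ".", attr = paste0("Parent=", tid))
    r <- c(r, list(ex))
    if (nrow(g$cds)) {
      ord <- if (g$strand == "+") order(g$cds[, 1L]) else order(-g$cds[, 1L])
      lens <- (g$cds[, 2L] - g$cds[, 1L])[ord]
      phase <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
      cd <- data.frame(chrom = g$chrom, start = g$cds[ord, 1L] + 1L,
                       end = g$cds[ord, 2L], strand = g$strand, type = "CDS",
                       phase = as.character(phase), attr = paste0("Parent=", tid))
      cd <- cd[order(cd$start), , drop = FALSE]
      r <- c(r, list(cd))
    }
    do.call(rbind, r)
  })
  tab <- do.call(rbind, rows)
  lines <- c("##gff-version 3",
             paste(tab$chrom, "wildtx", tab$type, tab$start, tab$end, ".",
                   tab$strand, tab$phase, tab$attr, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
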