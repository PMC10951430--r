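# Container classes for hierarchical gene annotations.
#
# An annotation source is held as three flat, mutually consistent tables
# (genes / transcripts / exons) rather than nested per-gene objects: every
# downstream operation (overlap scans, merging, classification) is a
# vectorized table operation. Coordinates are 1-based inclusive throughout;
# chrom is an opaque string so unplaced scaffolds need no special handling.

#' Build an annotation source from an exon table
#'
#' The exon table is the ground truth; transcript and gene records (spans,
#' TSS, exon counts, mono-exonic flags) are derived from it. Per-gene raw
#' biotypes are supplied separately and normalized with `biotype_map`.
#'
#' @param name Source name (e.g. `"refseq"`).
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive; strand `"+"` or `"-"`).
#' @param gene_biotypes Named character vector or data.frame
#'   (`gene_id`, `raw_biotype`) giving each gene's raw biotype; genes
#'   missing from it get class `"other"`.
#' @param priority Integer rank, 1 = highest.
#' @param biotype_map Mapping table for [normalize_biotype()].
#' @return An object of class `annotation_source` with elements `name`,
#'   `priority`, `genes`, `transcripts`, `exons`.
#' @export
annotation_source <- function(name, exons, gene_biotypes = NULL, priority = 1L,
                              biotype_map = biotype_class_map()) {
  required <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols)) {
    .stopf("exon table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  exons <- as.data.frame(exons)[required]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons)) {
    if (any(exons$start < 1L)) .stopf("exon start below 1")
    if (any(exons$end < exons$start)) .stopf("exon end before start")
    if (!all(exons$strand %in% c("+", "-"))) .stopf("strand must be '+' or '-'")
  }
  exons <- .reset_rownames(.order_exons(exons))

  # transcript-level consistency: one chrom/strand per transcript,
  # non-overlapping exons
  if (nrow(exons)) {
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (tx in names(by_tx)) {
      i <- by_tx[[tx]]
      if (length(unique(exons$chrom[i])) > 1L || length(unique(exons$strand[i])) > 1L) {
        .stopf("transcript %s mixes chromosomes or strands across its exons", tx)
      }
      s <- exons$start[i]; e <- exons$end[i]
      if (length(i) > 1L && any(s[-1] <= e[-length(e)])) {
        .stopf("transcript %s has overlapping exons", tx)
      }
    }
  }

  transcripts <- .derive_transcripts(exons)
  genes <- .derive_genes(exons, transcripts)

  # gene-level consistency: transcripts of a gene share chrom and strand
  if (anyDuplicated(paste(transcripts$gene_id, transcripts$transcript_id))) {
    .stopf("duplicate transcript ids within source %s", name)
  }
  bad <- tapply(paste(transcripts$chrom, transcripts$strand), transcripts$gene_id,
                function(v) length(unique(v)) > 1L)
  if (any(unlist(bad))) {
    .stopf("gene(s) %s mix chromosomes or strands across transcripts",
           paste(names(bad)[unlist(bad)], collapse = ", "))
  }

  raw <- .gene_biotype_vector(gene_biotypes, genes$gene_id)
  genes$raw_biotype <- unname(raw[genes$gene_id])
  genes$biotype_class <- normalize_biotype(genes$raw_biotype, biotype_map)

  structure(
    list(name = name, priority = as.integer(priority),
         genes = .reset_rownames(genes), transcripts = .reset_rownames(transcripts),
         exons = exons),
    class = "annotation_source"
  )
}

.gene_biotype_vector <- function(gene_biotypes, gene_ids) {
  if (is.null(gene_biotypes)) {
    out <- rep(NA_character_, length(gene_ids))
    names(out) <- gene_ids
    return(out)
  }
  if (is.data.frame(gene_biotypes)) {
    out <- gene_biotypes$raw_biotype[match(gene_ids, gene_biotypes$gene_id)]
  } else {
    out <- unname(gene_biotypes[gene_ids])
  }
  names(out) <- gene_ids
  out
}

# TSS of a transcript: start of the first exon on "+", end of the last on "-".
.derive_transcripts <- function(exons) {
  if (!nrow(exons)) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_exons = integer(), tss = integer(),
                      stringsAsFactors = FALSE))
  }
  idx <- split(seq_len(nrow(exons)), exons$transcript_id)
  tx <- data.frame(
    transcript_id = names(idx),
    gene_id = vapply(idx, function(i) exons$gene_id[i[1]], character(1)),
    chrom = vapply(idx, function(i) exons$chrom[i[1]], character(1)),
    strand = vapply(idx, function(i) exons$strand[i[1]], character(1)),
    start = vapply(idx, function(i) min(exons$start[i]), integer(1)),
    end = vapply(idx, function(i) max(exons$end[i]), integer(1)),
    n_exons = lengths(idx),
    stringsAsFactors = FALSE
  )
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  .reset_rownames(tx[order(tx$chrom, tx$start, tx$transcript_id), ])
}

.derive_genes <- function(exons, transcripts) {
  if (!nrow(transcripts)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      n_transcripts = integer(), n_exons = integer(),
                      monoexonic = logical(), stringsAsFactors = FALSE))
  }
  idx <- split(seq_len(nrow(transcripts)), transcripts$gene_id)
  g <- data.frame(
    gene_id = names(idx),
    chrom = vapply(idx, function(i) transcripts$chrom[i[1]], character(1)),
    strand = vapply(idx, function(i) transcripts$strand[i[1]], character(1)),
    start = vapply(idx, function(i) min(transcripts$start[i]), integer(1)),
    end = vapply(idx, function(i) max(transcripts$end[i]), integer(1)),
    n_transcripts = lengths(idx),
    n_exons = vapply(idx, function(i) {
      sum(transcripts$n_exons[i])
    }, integer(1)),
    monoexonic = vapply(idx, function(i) all(transcripts$n_exons[i] == 1L), logical(1)),
    stringsAsFactors = FALSE
  )
  .order_genes(.reset_rownames(g))
}

#' @export
print.annotation_source <- function(x, ...) {
  cat(sprintf("<annotation_source> %s (priority %d)\n", x$name, x$priority))
  cat(sprintf("  %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  tab <- table(x$genes$biotype_class)
  if (length(tab)) {
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of genes in an annotation source or merged atlas
#' @param x `annotation_source` or `merged_atlas`.
#' @return Integer.
#' @export
n_genes <- function(x) nrow(x$genes)

# exon rows of one gene / one transcript (internal accessors)
.gene_exons <- function(x, gene_id) {
  x$exons[x$exons$gene_id == gene_id, , drop = FALSE]
}

.transcript_exons <- function(x, transcript_id) {
  x$exons[x$exons$transcript_id == transcript_id, , drop = FALSE]
}
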