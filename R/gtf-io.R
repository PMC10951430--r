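# GTF / BED input-output.
#
# Reading goes through rtracklayer (both Ensembl-style `gene_biotype` and
# RefSeq/GENCODE-style `gene_type` attribute keys are accepted); a cheap
# pre-scan restores the line-number error reporting that a DOM-style reader
# cannot give. Writing is a small formatter so the emitted attribute layout
# is fixed and round-trips exactly through the reader.

#' Read a GTF file into an annotation source
#'
#' Exon records are attached to their transcripts; transcript records
#' without any exon line are synthesized as single-exon transcripts over
#' their own span (likewise gene records without transcripts). Genes whose
#' biotype attribute is missing or unrecognized get class `"other"`.
#'
#' @param path GTF file path (1-based inclusive coordinates).
#' @param source_name Name recorded for this source.
#' @param priority Integer priority rank (1 = highest).
#' @param biotype_map Mapping table for [normalize_biotype()].
#' @return An [annotation_source()].
#' @export
read_gtf <- function(path, source_name, priority = 1L,
                     biotype_map = biotype_class_map()) {
  if (!file.exists(path)) .stopf("GTF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    .stopf("malformed GTF record at line %d of %s (expected 9 tab-separated fields)",
           which(body)[which(nfield != 9L)[1]], path)
  }
  if (!any(body)) {
    return(annotation_source(source_name, .empty_exon_table(),
                             priority = priority, biotype_map = biotype_map))
  }

  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  for (col in c("type", "gene_id", "transcript_id")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df$type <- as.character(df$type)

  bio_col <- intersect(c("gene_biotype", "gene_type", "biotype"), names(df))
  df$.raw_biotype <- if (length(bio_col)) as.character(df[[bio_col[1]]]) else NA_character_

  if (anyNA(df$gene_id)) .stopf("GTF %s has records without a gene_id attribute", path)

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) && anyNA(ex$transcript_id)) {
    .stopf("GTF %s has exon records without a transcript_id attribute", path)
  }
  tx <- df[df$type == "transcript", , drop = FALSE]

  # transcripts with no exon children become single-exon over their own span
  orphan_tx <- tx[!(tx$transcript_id %in% ex$transcript_id), , drop = FALSE]
  # gene records with no transcript and no exon children get one of each
  gn <- df[df$type == "gene", , drop = FALSE]
  known_genes <- unique(c(ex$gene_id, tx$gene_id))
  orphan_gn <- gn[!(gn$gene_id %in% known_genes), , drop = FALSE]
  if (nrow(orphan_gn)) {
    orphan_gn$transcript_id <- paste0(orphan_gn$gene_id, ".t1")
  }

  exons <- rbind(
    data.frame(gene_id = ex$gene_id, transcript_id = ex$transcript_id,
               chrom = ex$seqnames, start = ex$start, end = ex$end,
               strand = ex$strand, stringsAsFactors = FALSE),
    data.frame(gene_id = orphan_tx$gene_id, transcript_id = orphan_tx$transcript_id,
               chrom = orphan_tx$seqnames, start = orphan_tx$start,
               end = orphan_tx$end, strand = orphan_tx$strand,
               stringsAsFactors = FALSE),
    data.frame(gene_id = orphan_gn$gene_id, transcript_id = orphan_gn$transcript_id,
               chrom = orphan_gn$seqnames, start = orphan_gn$start,
               end = orphan_gn$end, strand = orphan_gn$strand,
               stringsAsFactors = FALSE)
  )

  # an exon must sit on its declared transcript's chrom and strand
  if (nrow(tx) && nrow(ex)) {
    m <- match(ex$transcript_id, tx$transcript_id)
    has_parent <- !is.na(m)
    bad <- has_parent & (ex$seqnames != tx$seqnames[m] | ex$strand != tx$strand[m])
    if (any(bad)) {
      .stopf("exon of transcript %s disagrees with its transcript's chrom/strand",
             ex$transcript_id[which(bad)[1]])
    }
  }

  # per-gene raw biotype: prefer the gene record, else any child record
  bio <- df[!is.na(df$.raw_biotype), c("gene_id", "type", ".raw_biotype")]
  bio <- bio[order(bio$gene_id, bio$type != "gene"), ]
  bio <- bio[!duplicated(bio$gene_id), ]
  gene_biotypes <- data.frame(gene_id = bio$gene_id,
                              raw_biotype = bio$.raw_biotype,
                              stringsAsFactors = FALSE)

  annotation_source(source_name, exons, gene_biotypes = gene_biotypes,
                    priority = priority, biotype_map = biotype_map)
}

.empty_exon_table <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Write an annotation source or merged atlas as GTF
#'
#' Emits gene, transcript and exon records sorted by chromosome then start.
#' Attributes carry `gene_id`, `transcript_id`, `gene_biotype` (the raw
#' biotype) and the provenance tag in column 2 (the source name; for a
#' merged atlas, each gene's accepting source). Re-reading with
#' [read_gtf()] reproduces the in-memory model.
#'
#' @param x `annotation_source` or `merged_atlas`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  UseMethod("write_gtf")
}

#' @export
write_gtf.annotation_source <- function(x, path) {
  src <- rep(x$name, nrow(x$genes))
  names(src) <- x$genes$gene_id
  .write_gtf_tables(x$genes, x$transcripts, x$exons, src, path,
                    header = sprintf("#!source %s", x$name))
}

#' @export
write_gtf.merged_atlas <- function(x, path) {
  src <- x$genes$source
  names(src) <- x$genes$gene_id
  .write_gtf_tables(x$genes, x$transcripts, x$exons, src, path,
                    header = sprintf("#!sources %s", paste(x$order, collapse = ",")))
}

.write_gtf_tables <- function(genes, transcripts, exons, src_of_gene, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (!nrow(genes)) return(invisible(path))

  bio <- genes$raw_biotype
  bio[is.na(bio)] <- genes$biotype_class[is.na(bio)]
  names(bio) <- genes$gene_id

  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type, start, end, strand, attrs)
  }
  g <- .order_genes(genes)
  rows <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    src <- src_of_gene[[gid]]
    ga <- sprintf('gene_id "%s"; gene_biotype "%s";', gid, bio[[gid]])
    rows <- c(rows, fmt(g$chrom[i], src, "gene", g$start[i], g$end[i], g$strand[i], ga))
    tx <- transcripts[transcripts$gene_id == gid, , drop = FALSE]
    tx <- tx[order(tx$start, tx$transcript_id), , drop = FALSE]
    for (j in seq_len(nrow(tx))) {
      tid <- tx$transcript_id[j]
      ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";', gid, tid, bio[[gid]])
      rows <- c(rows, fmt(tx$chrom[j], src, "transcript", tx$start[j], tx$end[j], tx$strand[j], ta))
      e <- exons[exons$transcript_id == tid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      for (k in seq_len(nrow(e))) {
        ea <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d"; gene_biotype "%s";',
                      gid, tid, k, bio[[gid]])
        rows <- c(rows, fmt(e$chrom[k], src, "exon", e$start[k], e$end[k], e$strand[k], ea))
      }
    }
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read CAGE peaks from a BED file
#'
#' BED half-open 0-based intervals are converted to the package's 1-based
#' inclusive convention on read. Peak strand is kept but ignored by
#' [cage_support()] (TSS-to-peak matching is strand-blind).
#'
#' @param path BED file (at least 3 columns).
#' @param slop Tolerance in bp added on both sides when matching TSSs
#'   (default 30).
#' @return Object of class `cage_peaks`: list with `peaks` (data.frame
#'   `chrom`, `start`, `end`, `strand`) and `slop`.
#' @export
read_cage_bed <- function(path, slop = 30L) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  cage_peaks(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE),
             slop = slop)
}

#' Construct a CAGE peak set from a data.frame
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally `strand`.
#' @param slop Matching tolerance in bp (>= 0).
#' @return Object of class `cage_peaks`.
#' @export
cage_peaks <- function(peaks, slop = 30L) {
  if (slop < 0) .stopf("slop must be >= 0")
  if (!all(c("chrom", "start", "end") %in% names(peaks))) {
    .stopf("peaks need columns chrom, start, end")
  }
  if (is.null(peaks$strand)) peaks$strand <- "*"
  structure(list(peaks = .reset_rownames(as.data.frame(peaks)), slop = as.integer(slop)),
            class = "cage_peaks")
}

#' @export
print.cage_peaks <- function(x, ...) {
  cat(sprintf("<cage_peaks> %d peaks, slop %d bp\n", nrow(x$peaks), x$slop))
  invisible(x)
}
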