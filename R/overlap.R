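# Strand-aware exon-overlap primitives and the source-comparison statistics
# built on them. Two transcripts overlap iff they share chrom and strand and
# some exon pair has >= 1 bp in common (1-based inclusive, so [1,100] and
# [100,200] touch at bp 100 and do overlap).

#' Do two transcripts share at least one exonic base on the same strand?
#'
#' @param a,b data.frames of exons (columns `chrom`, `strand`, `start`,
#'   `end`), each describing one transcript (or, since all transcripts of a
#'   gene share chrom and strand, the pooled exons of one gene).
#' @return Logical scalar.
#' @examples
#' a <- data.frame(chrom = "1", strand = "+", start = 1, end = 100)
#' b <- data.frame(chrom = "1", strand = "+", start = 100, end = 200)
#' exons_overlap(a, b)  # TRUE: bp 100 is shared
#' @export
exons_overlap <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(FALSE)
  if (a$chrom[1] != b$chrom[1] || a$strand[1] != b$strand[1]) return(FALSE)
  for (i in seq_len(nrow(a))) {
    if (any(a$start[i] <= b$end & a$end[i] >= b$start)) return(TRUE)
  }
  FALSE
}

#' Accepted genes conflicting with a candidate gene
#'
#' A conflict is an accepted gene with at least one transcript exon-
#' overlapping a transcript of the candidate (same strand). With
#' `same_class_only = TRUE` (the default used for merging) only accepted
#' genes of the candidate's biotype class are considered, which is what
#' lets e.g. a miRNA nested in a protein-coding exon be added.
#'
#' @param candidate One-row slice of a source's gene table, or a gene id
#'   together with `source` supplied.
#' @param source The `annotation_source` (or `merged_atlas`) holding the
#'   candidate's exons. If `candidate` is a character id it is looked up here.
#' @param catalog `annotation_source` or `merged_atlas` of accepted genes.
#' @param same_class_only Restrict conflicts to the candidate's class.
#' @return Character vector of conflicting accepted gene ids (sorted).
#' @export
gene_conflicts <- function(candidate, source, catalog, same_class_only = TRUE) {
  if (is.character(candidate)) {
    candidate <- source$genes[source$genes$gene_id == candidate, , drop = FALSE]
  }
  if (nrow(candidate) != 1L) .stopf("candidate must identify exactly one gene")
  cand_ex <- .gene_exons(source, candidate$gene_id)
  genes <- catalog$genes
  if (same_class_only) {
    genes <- genes[genes$biotype_class == candidate$biotype_class, , drop = FALSE]
  }
  genes <- genes[genes$chrom == candidate$chrom & genes$strand == candidate$strand &
                   genes$start <= max(cand_ex$end) & genes$end >= min(cand_ex$start), ,
                 drop = FALSE]
  if (!nrow(genes)) return(character(0))
  ex <- catalog$exons[catalog$exons$gene_id %in% genes$gene_id, , drop = FALSE]
  hit <- logical(nrow(cand_ex))
  conflicting <- character(0)
  for (gid in unique(ex$gene_id)) {
    ge <- ex[ex$gene_id == gid, , drop = FALSE]
    if (exons_overlap(cand_ex, ge)) conflicting <- c(conflicting, gid)
  }
  sort(conflicting)
}

#' Fraction of class genes in one source exon-overlapping another source
#'
#' For each gene of `biotype_class` in `a`, tests whether it exon-overlaps
#' (same strand, >= 1 bp) at least one gene of that class in `b`.
#' Asymmetric by construction.
#'
#' @param a,b `annotation_source` objects.
#' @param biotype_class One of [BIOTYPE_CLASSES].
#' @return Fraction in `[0, 1]` (`NaN` when `a` has no gene of the class).
#' @export
overlap_rate <- function(a, b, biotype_class) {
  ga <- a$genes[a$genes$biotype_class == biotype_class, , drop = FALSE]
  gb <- b$genes[b$genes$biotype_class == biotype_class, , drop = FALSE]
  if (!nrow(ga)) return(NaN)
  if (!nrow(gb)) return(0)
  eb <- b$exons[b$exons$gene_id %in% gb$gene_id, , drop = FALSE]
  hits <- vapply(ga$gene_id, function(gid) {
    ea <- .gene_exons(a, gid)
    cand <- gb[gb$chrom == ea$chrom[1] & gb$strand == ea$strand[1] &
                 gb$start <= max(ea$end) & gb$end >= min(ea$start), , drop = FALSE]
    for (pid in cand$gene_id) {
      if (exons_overlap(ea, eb[eb$gene_id == pid, , drop = FALSE])) return(TRUE)
    }
    FALSE
  }, logical(1))
  mean(hits)
}

#' CAGE support of transcription start sites, per biotype class
#'
#' A transcript's TSS is supported when it lies within `slop` bp of a CAGE
#' peak, i.e. inside `[peak_start - slop, peak_end + slop]`. Peak strand is
#' ignored. Returns, for each biotype class present in the source, the
#' fraction of its transcripts with a supported TSS.
#'
#' @param source An `annotation_source`.
#' @param peaks A [cage_peaks()] object (its `slop` is used).
#' @return Named numeric vector of per-class fractions; attribute
#'   `"supported"` carries the per-transcript logical vector.
#' @export
cage_support <- function(source, peaks) {
  tx <- source$transcripts
  if (!nrow(tx)) return(stats::setNames(numeric(0), character(0)))
  p <- peaks$peaks
  slop <- peaks$slop
  tss_gr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$tss, tx$tss))
  peak_gr <- GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(pmax(1L, p$start - slop), p$end + slop))
  supported <- GenomicRanges::countOverlaps(tss_gr, peak_gr, ignore.strand = TRUE) > 0L
  cls <- source$genes$biotype_class[match(tx$gene_id, source$genes$gene_id)]
  out <- tapply(supported, cls, mean)
  res <- as.numeric(out)
  names(res) <- names(out)
  attr(res, "supported") <- stats::setNames(supported, tx$transcript_id)
  res
}
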