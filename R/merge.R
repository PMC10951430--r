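# Sequential multi-source aggregation.
#
# Source 1 (highest priority) is accepted wholesale; every later gene locus
# is accepted iff none of its transcripts exon-overlaps (same strand, >= 1
# bp) a transcript already in the growing catalog, the comparison being
# restricted to the candidate's biotype class by default. Rejection is
# whole-locus: if any transcript of a candidate conflicts, the entire gene
# is dropped (no transcript grafting). Rejected genes are logged together
# with the accepted genes they collided with, and their native ids are
# recorded as overlap-based cross-references of those accepted genes.

#' Merge annotation sources in priority order into an enriched atlas
#'
#' @param sources List of [annotation_source()] objects; processed in
#'   increasing `priority` (ties broken by list order). Source names must be
#'   unique.
#' @param same_class_only Evaluate conflicts within the candidate's biotype
#'   class only (default). `FALSE` gives the strict all-vs-all mode in which
#'   any same-strand exon overlap, regardless of class, is a conflict.
#' @return Object of class `merged_atlas`: tables `genes` (with `source`
#'   and `native_id` columns), `transcripts`, `exons`; `order` (source
#'   names as merged); `rejections` (data.frame `gene_id`, `source`,
#'   `conflicting_ids`); `xref` (data.frame `gene_id`, `source`,
#'   `native_id`, `relation` where relation is `"native"` for the accepting
#'   source's own id and `"overlap"` for ids of later-source genes rejected
#'   because they overlapped this gene).
#' @export
merge_annotations <- function(sources, same_class_only = TRUE) {
  if (!length(sources)) .stopf("need at least one source")
  if (!all(vapply(sources, inherits, logical(1), "annotation_source"))) {
    .stopf("all elements must be annotation_source objects")
  }
  nm <- vapply(sources, `[[`, character(1), "name")
  if (anyDuplicated(nm)) .stopf("duplicate source names: %s",
                                paste(nm[duplicated(nm)], collapse = ", "))
  sources <- sources[order(vapply(sources, `[[`, integer(1), "priority"))]
  nm <- vapply(sources, `[[`, character(1), "name")

  idx <- new.env(parent = emptyenv())
  reg <- function(key, exons, gid) {
    cur <- idx[[key]] %||% list(start = integer(0), end = integer(0), gene = character(0))
    idx[[key]] <- list(start = c(cur$start, exons$start),
                       end = c(cur$end, exons$end),
                       gene = c(cur$gene, rep(gid, nrow(exons))))
  }
  key_of <- function(chrom, strand, class) {
    if (same_class_only) paste(chrom, strand, class, sep = "|")
    else paste(chrom, strand, sep = "|")
  }
  lookup <- function(key, exons) {
    cur <- idx[[key]]
    if (is.null(cur)) return(character(0))
    hit <- logical(length(cur$gene))
    for (i in seq_len(nrow(exons))) {
      hit <- hit | (cur$start <= exons$end[i] & cur$end >= exons$start[i])
    }
    unique(cur$gene[hit])
  }

  acc_genes <- list(); acc_tx <- list(); acc_ex <- list()
  rej <- list(); xref_native <- list(); xref_overlap <- list()
  used_ids <- new.env(parent = emptyenv())

  for (s in seq_along(sources)) {
    src <- sources[[s]]
    g <- .order_genes(src$genes)
    for (i in seq_len(nrow(g))) {
      gid <- g$gene_id[i]
      cand_ex <- .gene_exons(src, gid)
      key <- key_of(g$chrom[i], g$strand[i], g$biotype_class[i])
      conflicts <- if (s == 1L) character(0) else sort(lookup(key, cand_ex))
      if (length(conflicts)) {
        rej[[length(rej) + 1L]] <- data.frame(
          gene_id = gid, source = src$name,
          conflicting_ids = paste(conflicts, collapse = ";"),
          stringsAsFactors = FALSE)
        xref_overlap[[length(xref_overlap) + 1L]] <- data.frame(
          gene_id = conflicts, source = src$name, native_id = gid,
          relation = "overlap", stringsAsFactors = FALSE)
        next
      }
      new_id <- gid
      if (!is.null(used_ids[[gid]])) {
        new_id <- paste0(gid, "__", src$name)
        message(sprintf("gene id %s from %s already in atlas; renamed to %s",
                        gid, src$name, new_id))
      }
      used_ids[[new_id]] <- TRUE
      grow <- g[i, , drop = FALSE]
      tx <- src$transcripts[src$transcripts$gene_id == gid, , drop = FALSE]
      ex <- cand_ex
      grow$native_id <- gid
      grow$gene_id <- new_id
      grow$source <- src$name
      tx$gene_id <- new_id
      ex$gene_id <- new_id
      if (new_id != gid) {
        tx$transcript_id <- paste0(tx$transcript_id, "__", src$name)
        ex$transcript_id <- paste0(ex$transcript_id, "__", src$name)
      }
      acc_genes[[length(acc_genes) + 1L]] <- grow
      acc_tx[[length(acc_tx) + 1L]] <- tx
      acc_ex[[length(acc_ex) + 1L]] <- ex
      xref_native[[length(xref_native) + 1L]] <- data.frame(
        gene_id = new_id, source = src$name, native_id = gid,
        relation = "native", stringsAsFactors = FALSE)
      reg(key, ex, new_id)
    }
  }

  genes <- .reset_rownames(.order_genes(do.call(rbind, acc_genes)))
  tx <- .reset_rownames(do.call(rbind, acc_tx))
  ex <- .reset_rownames(.order_exons(do.call(rbind, acc_ex)))
  empty_rej <- data.frame(gene_id = character(), source = character(),
                          conflicting_ids = character(), stringsAsFactors = FALSE)
  rejections <- if (length(rej)) .reset_rownames(do.call(rbind, rej)) else empty_rej
  xref <- .reset_rownames(do.call(rbind, c(xref_native, xref_overlap)))
  # keep only overlap xrefs pointing at genes that really are in the atlas
  xref <- xref[xref$gene_id %in% genes$gene_id, , drop = FALSE]
  xref <- xref[order(xref$gene_id, xref$relation, xref$source), , drop = FALSE]

  structure(list(genes = genes, transcripts = tx, exons = ex,
                 order = nm, rejections = rejections,
                 xref = .reset_rownames(xref),
                 same_class_only = same_class_only),
            class = "merged_atlas")
}

#' @export
print.merged_atlas <- function(x, ...) {
  cat(sprintf("<merged_atlas> %d genes from %d sources (%s)\n",
              nrow(x$genes), length(x$order), paste(x$order, collapse = " > ")))
  tab <- table(x$genes$biotype_class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  %d rejected loci logged\n", nrow(x$rejections)))
  invisible(x)
}

#' Convert a merged atlas back to a single annotation source
#'
#' Useful for idempotence checks (merging an atlas with itself) and for
#' re-using source-level operations on the merged catalog.
#'
#' @param atlas A `merged_atlas`.
#' @param name,priority Name and priority of the resulting source.
#' @return An [annotation_source()].
#' @export
as_annotation_source <- function(atlas, name = "atlas", priority = 1L) {
  bios <- data.frame(gene_id = atlas$genes$gene_id,
                     raw_biotype = atlas$genes$raw_biotype,
                     stringsAsFactors = FALSE)
  annotation_source(name, atlas$exons, gene_biotypes = bios, priority = priority)
}
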