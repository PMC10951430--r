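# Positional classification of genes relative to their closest
# protein-coding gene, FEELnc-style: genic (exonic/intronic, sense/
# antisense) when spans intersect, otherwise intergenic with an
# orientation (same-strand up/down, divergent head-to-head, convergent
# tail-to-tail) and a distance.

.RELATION_RANK <- c(genic_exonic = 1L, genic_intronic = 2L, intergenic = 3L)

#' Classify one focal transcript against one PCG transcript
#'
#' Genic when the two transcript spans intersect: `genic_exonic` if at
#' least one focal exon shares >= 1 bp with a partner exon (irrespective of
#' strand), else `genic_intronic`; direction is `sense` when strands are
#' equal, `antisense` otherwise. When the spans are disjoint the pair is
#' `intergenic` with distance the gap between the nearest span ends;
#' orientation on equal strands is `same_strand_up` when the focal
#' transcript lies on the 5' side of the partner's transcription direction
#' (`same_strand_down` on the 3' side), and on opposite strands
#' `divergent` when the two TSSs face each other (head-to-head) or
#' `convergent` when the two 3' ends do (tail-to-tail).
#'
#' @param focal,partner Exon data.frames (`chrom`, `strand`, `start`,
#'   `end`) of one transcript each, on the same chromosome.
#' @return List with `relation`, `direction` (genic) or `orientation`
#'   (intergenic), `distance` (0 for genic); `NULL` when the transcripts
#'   sit on different chromosomes.
#' @export
classify_transcript_pair <- function(focal, partner) {
  if (focal$chrom[1] != partner$chrom[1]) return(NULL)
  fs <- min(focal$start); fe <- max(focal$end)
  ps <- min(partner$start); pe <- max(partner$end)
  same_strand <- focal$strand[1] == partner$strand[1]

  if (fs <= pe && fe >= ps) {
    exonic <- FALSE
    for (i in seq_len(nrow(focal))) {
      if (any(focal$start[i] <= partner$end & focal$end[i] >= partner$start)) {
        exonic <- TRUE
        break
      }
    }
    return(list(relation = if (exonic) "genic_exonic" else "genic_intronic",
                direction = if (same_strand) "sense" else "antisense",
                orientation = NA_character_, distance = 0L))
  }

  focal_left <- fe < ps
  distance <- if (focal_left) ps - fe else fs - pe
  if (same_strand) {
    # partner transcribes left->right on "+": upstream side is its left
    upstream_side_left <- partner$strand[1] == "+"
    orientation <- if (focal_left == upstream_side_left) "same_strand_up" else "same_strand_down"
  } else {
    # focal left of partner: heads face iff focal on "-" (TSS at its right
    # end) and partner on "+" (TSS at its left end); mirrored otherwise
    facing_tss <- if (focal_left) {
      focal$strand[1] == "-" && partner$strand[1] == "+"
    } else {
      focal$strand[1] == "+" && partner$strand[1] == "-"
    }
    orientation <- if (facing_tss) "divergent" else "convergent"
  }
  list(relation = "intergenic", direction = NA_character_,
       orientation = orientation, distance = as.integer(distance))
}

# best transcript-pair call between a focal gene and one partner gene
.best_pair_for_partner <- function(catalog, focal_tx_ids, partner_tx_ids) {
  best <- NULL
  for (ft in focal_tx_ids) {
    fe <- .transcript_exons(catalog, ft)
    for (pt in partner_tx_ids) {
      pe <- .transcript_exons(catalog, pt)
      cl <- classify_transcript_pair(fe, pe)
      if (is.null(cl)) next
      if (is.null(best) ||
          .RELATION_RANK[[cl$relation]] < .RELATION_RANK[[best$relation]] ||
          (.RELATION_RANK[[cl$relation]] == .RELATION_RANK[[best$relation]] &&
             cl$distance < best$distance)) {
        best <- cl
      }
    }
  }
  best
}

#' Gene-level classification against the closest partner-class gene
#'
#' Every focal-class gene is evaluated against all partner-class genes
#' whose span lies within `window` bp of the focal span; among all
#' (focal transcript x partner transcript) pairs the best call wins under
#' the precedence genic_exonic > genic_intronic > intergenic, then smallest
#' distance, then lexicographically smallest partner gene id. Reported
#' distance is measured between gene spans (0 for genic calls); genes with
#' no partner within the window are returned unclassified (`NA` partner).
#'
#' @param atlas `merged_atlas` (or `annotation_source`).
#' @param focal_class Biotype class of the focal genes (default
#'   `"lncRNA"`).
#' @param partner_class Biotype class of the partners (default `"pcg"`).
#' @param window Maximum span-to-span gap in bp (default 100 kb).
#' @return data.frame `focal_id`, `partner_id`, `relation`, `direction`,
#'   `orientation`, `distance`, `window`.
#' @export
classify_genes <- function(atlas, focal_class = "lncRNA", partner_class = "pcg",
                           window = 1e5) {
  g <- atlas$genes
  focal <- g[g$biotype_class == focal_class, , drop = FALSE]
  partners <- g[g$biotype_class == partner_class, , drop = FALSE]
  tx_by_gene <- split(atlas$transcripts$transcript_id, atlas$transcripts$gene_id)

  rows <- lapply(seq_len(nrow(focal)), function(i) {
    f <- focal[i, ]
    cand <- partners[partners$gene_id != f$gene_id & partners$chrom == f$chrom, , drop = FALSE]
    if (nrow(cand)) {
      gap <- pmax(0L, pmax(cand$start - f$end, f$start - cand$end))
      cand <- cand[gap <= window, , drop = FALSE]
      gap <- gap[gap <= window]
    } else {
      gap <- integer(0)
    }
    best <- NULL; best_partner <- NA_character_; best_gap <- NA_integer_
    for (j in seq_len(nrow(cand))) {
      cl <- .best_pair_for_partner(atlas, tx_by_gene[[f$gene_id]],
                                   tx_by_gene[[cand$gene_id[j]]])
      if (is.null(cl)) next
      # span gap; if spans touch while every transcript pair is disjoint,
      # fall back to the best transcript pair's gap so intergenic distances
      # stay positive
      cl_dist <- if (cl$relation != "intergenic") 0L
        else if (gap[j] > 0L) gap[j] else cl$distance
      better <- is.null(best) ||
        .RELATION_RANK[[cl$relation]] < .RELATION_RANK[[best$relation]] ||
        (.RELATION_RANK[[cl$relation]] == .RELATION_RANK[[best$relation]] &&
           (cl_dist < best_gap ||
              (cl_dist == best_gap && cand$gene_id[j] < best_partner)))
      if (better) {
        best <- cl; best_partner <- cand$gene_id[j]; best_gap <- cl_dist
      }
    }
    if (is.null(best)) {
      data.frame(focal_id = f$gene_id, partner_id = NA_character_,
                 relation = NA_character_, direction = NA_character_,
                 orientation = NA_character_, distance = NA_integer_,
                 window = as.integer(window), stringsAsFactors = FALSE)
    } else {
      data.frame(focal_id = f$gene_id, partner_id = best_partner,
                 relation = best$relation, direction = best$direction,
                 orientation = best$orientation, distance = best_gap,
                 window = as.integer(window), stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(focal_id = character(), partner_id = character(),
               relation = character(), direction = character(),
               orientation = character(), distance = integer(),
               window = integer(), stringsAsFactors = FALSE)
  }
  .reset_rownames(out)
}

#' Tabulate miRNA host genes
#'
#' Every miRNA-class gene nested in (or exon-overlapping) a lncRNA or
#' protein-coding gene is reported with its host and the relation
#' (`exonic` when a miRNA exon shares >= 1 bp with a host exon, else
#' `intronic`). When several hosts overlap a miRNA the smallest enclosing
#' span wins (fully containing hosts are preferred). A host can appear in
#' several rows (one per hosted miRNA).
#'
#' @param atlas `merged_atlas` (or `annotation_source`).
#' @return data.frame `mirna_id`, `host_gene_id`, `host_class`, `relation`.
#' @export
mirna_hosts <- function(atlas) {
  g <- atlas$genes
  mir <- g[g$biotype_class == "miRNA", , drop = FALSE]
  hosts <- g[g$biotype_class %in% c("lncRNA", "pcg"), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(mir))) {
    m <- mir[i, ]
    cand <- hosts[hosts$chrom == m$chrom & hosts$start <= m$end & hosts$end >= m$start, ,
                  drop = FALSE]
    if (!nrow(cand)) next
    contains <- cand$start <= m$start & cand$end >= m$end
    if (any(contains)) cand <- cand[contains, , drop = FALSE]
    cand <- cand[order(cand$end - cand$start, cand$gene_id), , drop = FALSE]
    host <- cand[1, ]
    me <- .gene_exons(atlas, m$gene_id)
    he <- .gene_exons(atlas, host$gene_id)
    exonic <- FALSE
    for (k in seq_len(nrow(me))) {
      if (any(me$start[k] <= he$end & me$end[k] >= he$start)) { exonic <- TRUE; break }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = m$gene_id, host_gene_id = host$gene_id,
      host_class = host$biotype_class,
      relation = if (exonic) "exonic" else "intronic",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(mirna_id = character(), host_gene_id = character(),
               host_class = character(), relation = character(),
               stringsAsFactors = FALSE)
  }
  .reset_rownames(out)
}

#' Pair each focal-class gene with its closest partner-class gene
#'
#' Thin wrapper over [classify_genes()] with the wide co-expression window
#' (default 1 Mb) that additionally labels each pair's configuration:
#' `"genic"` for genic relations, otherwise the intergenic orientation.
#' Unpaired genes (no partner within the window) are dropped; their count
#' is kept in the `"n_unpaired"` attribute.
#'
#' @inheritParams classify_genes
#' @param window Default 1 Mb.
#' @return data.frame `focal_id`, `partner_id`, `pair_type`,
#'   `configuration`, `relation`, `distance`.
#' @export
pair_for_coexpression <- function(atlas, focal_class = "lncRNA",
                                  partner_class = "pcg", window = 1e6) {
  cl <- classify_genes(atlas, focal_class, partner_class, window = window)
  unpaired <- sum(is.na(cl$partner_id))
  cl <- cl[!is.na(cl$partner_id), , drop = FALSE]
  out <- data.frame(
    focal_id = cl$focal_id, partner_id = cl$partner_id,
    pair_type = paste(focal_class, partner_class, sep = ":"),
    configuration = ifelse(cl$relation == "intergenic", cl$orientation, "genic"),
    relation = cl$relation, distance = cl$distance,
    stringsAsFactors = FALSE)
  attr(out, "n_unpaired") <- unpaired
  .reset_rownames(out)
}
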