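# Builders for tiny hand-made annotations, plus independent brute-force
# oracles. The oracles re-derive overlap, merging and positional calls from
# first principles (plain nested loops over exon pairs) and share no code
# with the package internals they check.

# exons: list of transcripts, each a list/matrix of c(start, end) pairs
make_gene <- function(id, chrom, strand, raw_biotype, transcripts) {
  rows <- list()
  for (j in seq_along(transcripts)) {
    tx <- transcripts[[j]]
    for (e in tx) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = id, transcript_id = sprintf("%s.t%d", id, j),
        chrom = chrom, start = e[1], end = e[2], strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  list(exons = do.call(rbind, rows),
       bio = data.frame(gene_id = id, raw_biotype = raw_biotype,
                        stringsAsFactors = FALSE))
}

make_source <- function(name, priority, genes) {
  annotation_source(name,
                    do.call(rbind, lapply(genes, `[[`, "exons")),
                    gene_biotypes = do.call(rbind, lapply(genes, `[[`, "bio")),
                    priority = priority)
}

# single-transcript convenience wrapper
g1 <- function(id, chrom, strand, bio, ...) {
  make_gene(id, chrom, strand, bio, list(list(...)))
}

# ---- independent overlap oracle -------------------------------------------

oracle_exons_overlap <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  if (a$strand[1] != b$strand[1]) return(FALSE)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (hi - lo + 1 >= 1) return(TRUE)
  }
  FALSE
}

# do any transcript pair of two genes overlap? (loops over transcripts)
oracle_genes_overlap <- function(src_a, gid_a, src_b, gid_b) {
  ea <- src_a$exons[src_a$exons$gene_id == gid_a, , drop = FALSE]
  eb <- src_b$exons[src_b$exons$gene_id == gid_b, , drop = FALSE]
  for (ta in unique(ea$transcript_id)) for (tb in unique(eb$transcript_id)) {
    if (oracle_exons_overlap(ea[ea$transcript_id == ta, , drop = FALSE],
                             eb[eb$transcript_id == tb, , drop = FALSE])) {
      return(TRUE)
    }
  }
  FALSE
}

# sequential merge oracle: O(n^2) all-vs-all against the growing catalog
oracle_merge_accepted <- function(sources, same_class_only = TRUE) {
  sources <- sources[order(sapply(sources, `[[`, "priority"))]
  accepted <- list()  # list of (source, gene_id, class)
  for (s in seq_along(sources)) {
    src <- sources[[s]]
    g <- src$genes[order(src$genes$chrom, src$genes$start, src$genes$gene_id), ]
    for (i in seq_len(nrow(g))) {
      ok <- TRUE
      if (s > 1L) {
        for (acc in accepted) {
          if (same_class_only && acc$class != g$biotype_class[i]) next
          if (oracle_genes_overlap(src, g$gene_id[i], acc$src, acc$gene_id)) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        accepted[[length(accepted) + 1L]] <- list(src = src, gene_id = g$gene_id[i],
                                                  class = g$biotype_class[i],
                                                  source = src$name)
      }
    }
  }
  data.frame(gene_id = sapply(accepted, `[[`, "gene_id"),
             source = sapply(accepted, `[[`, "source"),
             stringsAsFactors = FALSE)
}

# ---- independent positional-classification oracle -------------------------

# classify one focal gene against every partner-class gene by exhaustive
# transcript-pair enumeration; returns partner id + relation or NA
oracle_classify_gene <- function(atlas, focal_id, partner_class, window) {
  g <- atlas$genes
  f <- g[g$gene_id == focal_id, ]
  partners <- g[g$biotype_class == partner_class & g$gene_id != focal_id &
                  g$chrom == f$chrom, , drop = FALSE]
  rank_of <- c(genic_exonic = 1, genic_intronic = 2, intergenic = 3)
  best <- NULL
  for (p in seq_len(nrow(partners))) {
    pg <- partners[p, ]
    gap <- max(0, pg$start - f$end, f$start - pg$end)
    if (gap > window) next
    ftx <- unique(atlas$transcripts$transcript_id[atlas$transcripts$gene_id == focal_id])
    ptx <- unique(atlas$transcripts$transcript_id[atlas$transcripts$gene_id == pg$gene_id])
    pair_best <- NULL
    for (ft in ftx) for (pt in ptx) {
      fe <- atlas$exons[atlas$exons$transcript_id == ft, , drop = FALSE]
      pe <- atlas$exons[atlas$exons$transcript_id == pt, , drop = FALSE]
      fs <- min(fe$start); fend <- max(fe$end)
      ps <- min(pe$start); pend <- max(pe$end)
      if (fs <= pend && fend >= ps) {
        ex <- FALSE
        for (i in seq_len(nrow(fe))) for (j in seq_len(nrow(pe))) {
          if (max(fe$start[i], pe$start[j]) <= min(fe$end[i], pe$end[j])) ex <- TRUE
        }
        rel <- if (ex) "genic_exonic" else "genic_intronic"
        d <- 0
      } else {
        rel <- "intergenic"
        d <- if (fend < ps) ps - fend else fs - pend
      }
      cand <- list(relation = rel, distance = d)
      if (is.null(pair_best) || rank_of[cand$relation] < rank_of[pair_best$relation] ||
          (rank_of[cand$relation] == rank_of[pair_best$relation] &&
             cand$distance < pair_best$distance)) {
        pair_best <- cand
      }
    }
    d_gene <- if (pair_best$relation == "intergenic") {
      if (gap > 0) gap else pair_best$distance
    } else 0
    cand <- list(partner = pg$gene_id, relation = pair_best$relation, distance = d_gene)
    if (is.null(best) || rank_of[cand$relation] < rank_of[best$relation] ||
        (rank_of[cand$relation] == rank_of[best$relation] &&
           (cand$distance < best$distance ||
              (cand$distance == best$distance && cand$partner < best$partner)))) {
      best <- cand
    }
  }
  best
}

# small random multi-source fixture via the package generator
random_fixture <- function(seed, n_sources = 2, pcg = 20, lnc = 15,
                           overlap = 0.3, mir_in = 2, mir_ex = 2) {
  spec <- fixture_spec(seed = seed, n_sources = n_sources,
                       genes_per_source = c(pcg = pcg, lncRNA = lnc),
                       overlap_fraction = overlap,
                       n_mirna_intronic = mir_in, n_mirna_exonic = mir_ex,
                       n_chroms = 2, chrom_length = 1e7)
  list(spec = spec, fx = generate_annotations(spec))
}

# closed-form BH step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# brute-force tau-b from concordant/discordant pair counting
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- (x[i] - x[j]) * (y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  ties <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}
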