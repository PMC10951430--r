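# Seeded synthetic fixtures: multi-source annotations with controlled
# overlap structure and expression matrices with planted tissue-specific,
# ubiquitous, sex-biased and co-regulated genes. Every generated object is
# accompanied by a truth table, and a fixed seed reproduces the outputs
# bit-for-bit.

#' Specification of a synthetic fixture
#'
#' Defaults describe the study conditions the package targets: a 47-tissue
#' expression panel, two projects per tissue with four samples each,
#' negative-binomial count noise (dispersion 0.1) on log-normally varying
#' library sizes, spike archetypes with a ~0.15 TPM background and
#' 100-fold single-tissue spikes, and multi-source annotations in which a
#' stated fraction of each later source's loci exon-overlap the previous
#' source.
#'
#' @param seed Integer RNG seed; fixed seed implies identical output.
#' @param n_sources Number of annotation sources (priority = list order).
#' @param genes_per_source Named integer vector of genes per biotype class
#'   in every source (classes `pcg` and/or `lncRNA`).
#' @param overlap_fraction Fraction of each later source's genes cloned
#'   from (and hence exon-overlapping) the previous source.
#' @param n_mirna_intronic,n_mirna_exonic miRNA genes planted inside
#'   same-strand introns of priority-1 PCGs / inside exons of priority-1
#'   lncRNAs; carried by the last source.
#' @param n_chroms,chrom_length Chromosome layout for placing loci.
#' @param n_tissues,projects_per_tissue,samples_per_project Expression
#'   panel design.
#' @param p_mono,mono_fold,p_poly,poly_size,poly_fold,p_sex,sex_log2fc
#'   Archetype mixture and effect sizes.
#' @param n_coexpr_pairs,latent_strength Co-regulated pairs sharing a
#'   latent per-tissue factor (log-scale SD `latent_strength`).
#' @param dispersion NB dispersion of the count noise.
#' @param libsize,libsize_sdlog Mean library size and log-scale SD.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_sources = 2L,
                         genes_per_source = c(pcg = 30L, lncRNA = 20L),
                         overlap_fraction = 0.3,
                         n_mirna_intronic = 3L,
                         n_mirna_exonic = 2L,
                         n_chroms = 2L,
                         chrom_length = 5e6,
                         n_tissues = 47L,
                         projects_per_tissue = 2L,
                         samples_per_project = 4L,
                         p_mono = 0.2, mono_fold = 100,
                         p_poly = 0.1, poly_size = 3L, poly_fold = 50,
                         p_sex = 0.05, sex_log2fc = 2,
                         n_coexpr_pairs = 5L, latent_strength = 1.5,
                         dispersion = 0.1,
                         libsize = 2e6, libsize_sdlog = 0.3) {
  spec <- as.list(environment())
  if (overlap_fraction < 0 || overlap_fraction > 1) .stopf("overlap_fraction must be in [0, 1]")
  if (!all(names(genes_per_source) %in% c("pcg", "lncRNA"))) {
    .stopf("genes_per_source supports classes pcg and lncRNA")
  }
  structure(spec, class = "fixture_spec")
}

# one random gene model within a slot; returns exon table rows
.random_gene_exons <- function(gene_id, chrom, slot_start, class) {
  strand <- sample(c("+", "-"), 1L)
  n_ex <- if (class == "lncRNA") sample(1:3, 1L) else sample(2:4, 1L)
  widths <- round(stats::runif(n_ex, 150, 800))
  gaps <- if (n_ex > 1L) round(stats::runif(n_ex - 1L, 600, 3000)) else integer(0)
  starts <- slot_start + cumsum(c(0L, widths[-n_ex] + gaps))
  ends <- starts + widths - 1L
  tx1 <- data.frame(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
                    chrom = chrom, start = starts, end = ends, strand = strand,
                    stringsAsFactors = FALSE)
  out <- tx1
  if (n_ex > 1L && stats::runif(1) < 0.4) {
    tx2 <- tx1[-nrow(tx1), , drop = FALSE]   # drops the last exon
    tx2$transcript_id <- paste0(gene_id, ".t2")
    out <- rbind(out, tx2)
  }
  out
}

#' Generate multi-source annotations with a controlled overlap structure
#'
#' Source 1 carries only novel loci. Each later source clones
#' `overlap_fraction` of its per-class quota from the previous source
#' (identical exon coordinates under new ids, hence guaranteed same-strand
#' exon overlaps) and fills the rest with novel loci in fresh slots.
#' miRNA genes are planted inside same-strand introns of priority-1 PCGs
#' and inside exons of priority-1 lncRNAs, and travel with the last source
#' so that merging has to decide their fate. The truth table records every
#' gene's role and planted relations.
#'
#' @param spec A [fixture_spec()].
#' @return List with `sources` (list of [annotation_source()]) and `truth`
#'   (data.frame `gene_id`, `source`, `biotype_class`, `role`
#'   (`novel`/`clone`/`mirna`), `overlaps`, `host_id`, `host_relation`).
#' @export
generate_annotations <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, .generate_annotations_impl(spec))
}

.generate_annotations_impl <- function(spec) {
  slot_w <- 30000L
  slots_per_chrom <- floor(spec$chrom_length / slot_w)
  classes <- names(spec$genes_per_source)
  n_clone <- if (spec$n_sources > 1L) round(spec$overlap_fraction * spec$genes_per_source) else 0L
  n_novel_total <- sum(spec$genes_per_source) +
    (spec$n_sources - 1L) * sum(spec$genes_per_source - n_clone) +
    spec$n_mirna_intronic + spec$n_mirna_exonic
  if (n_novel_total > spec$n_chroms * slots_per_chrom) {
    .stopf("cannot place %d loci on %d chromosome(s) of %g bp",
           n_novel_total, spec$n_chroms, spec$chrom_length)
  }
  slot <- 0L
  next_slot <- function() {
    slot <<- slot + 1L
    chrom <- paste0("chr", ((slot - 1L) %% spec$n_chroms) + 1L)
    pos <- 1L + ((slot - 1L) %/% spec$n_chroms) * slot_w + round(stats::runif(1, 0, 4000))
    list(chrom = chrom, start = as.integer(pos))
  }

  raw_of <- c(pcg = "protein_coding", lncRNA = "lncRNA", miRNA = "miRNA")
  sources <- vector("list", spec$n_sources)
  truth <- list()
  prev_genes <- NULL  # data.frame gene_id/class of previous source

  for (s in seq_len(spec$n_sources)) {
    src_name <- paste0("source", s)
    exons <- list()
    bios <- list()
    cur_genes <- list()
    gi <- 0L
    for (cls in classes) {
      n_cls <- spec$genes_per_source[[cls]]
      n_cl <- if (s > 1L) n_clone[[cls]] else 0L
      clone_from <- if (n_cl > 0L) {
        pool <- prev_genes$gene_id[prev_genes$class == cls]
        sample(pool, min(n_cl, length(pool)))
      } else character(0)
      for (i in seq_len(n_cls)) {
        gi <- gi + 1L
        gid <- sprintf("S%dG%04d", s, gi)
        if (i <= length(clone_from)) {
          tpl <- clone_from[i]
          ex <- sources[[s - 1L]]$exons
          ex <- ex[ex$gene_id == tpl, , drop = FALSE]
          ex$transcript_id <- sub(tpl, gid, ex$transcript_id, fixed = TRUE)
          ex$gene_id <- gid
          role <- "clone"; over <- tpl
        } else {
          sl <- next_slot()
          ex <- .random_gene_exons(gid, sl$chrom, sl$start, cls)
          role <- "novel"; over <- ""
        }
        exons[[length(exons) + 1L]] <- ex
        bios[[length(bios) + 1L]] <- data.frame(gene_id = gid, raw_biotype = raw_of[[cls]],
                                                stringsAsFactors = FALSE)
        cur_genes[[length(cur_genes) + 1L]] <- data.frame(gene_id = gid, class = cls,
                                                          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, source = src_name, biotype_class = cls, role = role,
          overlaps = over, host_id = "", host_relation = "",
          stringsAsFactors = FALSE)
      }
    }

    # miRNAs ride with the last source, nested in priority-1 hosts
    if (s == spec$n_sources && (spec$n_mirna_intronic + spec$n_mirna_exonic) > 0L) {
      host_src <- sources[[1L]] %||% NULL
      host_exons <- if (s == 1L) do.call(rbind, exons) else sources[[1L]]$exons
      host_truth_src <- "source1"
      mir_rows <- .plant_mirnas(spec, host_exons,
                                if (s == 1L) do.call(rbind, bios) else NULL,
                                sources, s)
      for (r in mir_rows) {
        gi <- gi + 1L
        gid <- sprintf("S%dMIR%03d", s, gi)
        ex <- r$exon
        ex$gene_id <- gid
        ex$transcript_id <- paste0(gid, ".t1")
        exons[[length(exons) + 1L]] <- ex
        bios[[length(bios) + 1L]] <- data.frame(gene_id = gid, raw_biotype = "miRNA",
                                                stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, source = src_name, biotype_class = "miRNA", role = "mirna",
          overlaps = "", host_id = r$host_id, host_relation = r$relation,
          stringsAsFactors = FALSE)
      }
    }

    sources[[s]] <- annotation_source(src_name, do.call(rbind, exons),
                                      gene_biotypes = do.call(rbind, bios),
                                      priority = s)
    prev_genes <- do.call(rbind, cur_genes)
  }

  list(sources = sources, truth = .reset_rownames(do.call(rbind, truth)))
}

# pick intron/exon sites in priority-1 hosts for planted miRNAs
.plant_mirnas <- function(spec, host_exons, host_bios, sources, s) {
  if (s == 1L) {
    bio <- host_bios
  } else {
    bio <- data.frame(gene_id = sources[[1L]]$genes$gene_id,
                      raw_biotype = sources[[1L]]$genes$raw_biotype,
                      stringsAsFactors = FALSE)
  }
  cls <- normalize_biotype(bio$raw_biotype)
  names(cls) <- bio$gene_id
  out <- list()

  # intronic: need a PCG transcript with an internal gap wide enough
  pcg_ids <- names(cls)[cls == "pcg"]
  placed <- 0L
  for (gid in sample(pcg_ids)) {
    if (placed >= spec$n_mirna_intronic) break
    ex <- host_exons[host_exons$gene_id == gid, , drop = FALSE]
    tx <- split(ex, ex$transcript_id)[[1]]
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) < 2L) next
    gap_start <- tx$end[1] + 1L; gap_end <- tx$start[2] - 1L
    if (gap_end - gap_start < 300L) next
    mid <- gap_start + 100L
    out[[length(out) + 1L]] <- list(
      exon = data.frame(gene_id = "", transcript_id = "", chrom = tx$chrom[1],
                        start = mid, end = mid + 89L, strand = tx$strand[1],
                        stringsAsFactors = FALSE),
      host_id = gid, relation = "intronic")
    placed <- placed + 1L
  }

  # exonic: inside a lncRNA exon wide enough
  lnc_ids <- names(cls)[cls == "lncRNA"]
  placed <- 0L
  for (gid in sample(lnc_ids)) {
    if (placed >= spec$n_mirna_exonic) break
    ex <- host_exons[host_exons$gene_id == gid, , drop = FALSE]
    wide <- ex[ex$end - ex$start >= 200L, , drop = FALSE]
    if (!nrow(wide)) next
    e <- wide[1, ]
    out[[length(out) + 1L]] <- list(
      exon = data.frame(gene_id = "", transcript_id = "", chrom = e$chrom,
                        start = e$start + 20L, end = e$start + 109L, strand = e$strand,
                        stringsAsFactors = FALSE),
      host_id = gid, relation = "exonic")
    placed <- placed + 1L
  }
  out
}

#' Generate a synthetic expression study over an atlas
#'
#' Each atlas gene is assigned an archetype (uniform background,
#' single-tissue spike, multi-tissue spike, sex-biased, or one half of a
#' co-regulated pair sharing a latent per-tissue factor); the expected-TPM
#' matrix is column-normalized to one million so planted absolute TPM
#' levels survive re-quantification; counts are drawn per sample from a
#' negative binomial around the expected proportions with log-normally
#' varying library sizes. Quantification lengths are the genes' exonic
#' union lengths.
#'
#' @param spec A [fixture_spec()].
#' @param atlas A `merged_atlas` (or `annotation_source`) whose genes are
#'   profiled.
#' @return List with `counts` (integer matrix genes x samples), `lengths`
#'   (named vector), `samples` (sample sheet data.frame), `truth`
#'   (per-gene archetype table) and `expected_tpm` (genes x tissues).
#' @export
generate_expression <- function(spec, atlas) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 1L, .generate_expression_impl(spec, atlas))
}

.generate_expression_impl <- function(spec, atlas) {
  genes <- atlas$genes
  gid <- genes$gene_id
  n_g <- length(gid)
  tissues <- sprintf("tissue_%02d", seq_len(spec$n_tissues))

  # exonic union length per gene (exons within a transcript are disjoint;
  # take the union across transcripts)
  lengths <- vapply(gid, function(g) {
    ex <- atlas$exons[atlas$exons$gene_id == g, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    sum(IRanges::width(ir))
  }, numeric(1))

  # sample sheet
  sheet <- do.call(rbind, lapply(tissues, function(tt) {
    do.call(rbind, lapply(seq_len(spec$projects_per_tissue), function(p) {
      data.frame(tissue = tt, project = sprintf("proj_%s_%d", tt, p),
                 sex = rep(c("M", "F"), length.out = spec$samples_per_project),
                 stringsAsFactors = FALSE)
    }))
  }))
  sheet$sample_id <- sprintf("s%04d", seq_len(nrow(sheet)))
  sheet <- sheet[, c("sample_id", "tissue", "project", "sex")]

  # archetype assignment (special archetypes only for pcg/lncRNA genes)
  eligible <- which(genes$biotype_class %in% c("pcg", "lncRNA"))
  archetype <- rep("uniform", n_g)
  partner <- rep(NA_character_, n_g)
  co_idx <- if (spec$n_coexpr_pairs > 0L && length(eligible) >= 2L * spec$n_coexpr_pairs) {
    sample(eligible, 2L * spec$n_coexpr_pairs)
  } else integer(0)
  if (length(co_idx)) {
    archetype[co_idx] <- "co_regulated"
    first <- co_idx[seq_len(length(co_idx) / 2L)]
    second <- co_idx[-seq_len(length(co_idx) / 2L)]
    partner[first] <- gid[second]
    partner[second] <- gid[first]
  }
  rest <- setdiff(eligible, co_idx)
  p_rest <- c(mono_spike = spec$p_mono, poly_spike = spec$p_poly,
              sex_biased = spec$p_sex)
  draw <- sample(c(names(p_rest), "uniform"), length(rest), replace = TRUE,
                 prob = c(p_rest, max(0, 1 - sum(p_rest))))
  archetype[rest] <- draw

  spike_tissues <- rep("", n_g)
  spike_fold <- rep(NA_real_, n_g)
  sex_tissue <- rep("", n_g)

  E <- matrix(0, nrow = n_g, ncol = spec$n_tissues, dimnames = list(gid, tissues))
  latent <- new.env(parent = emptyenv())
  for (i in seq_len(n_g)) {
    a <- archetype[i]
    if (a == "mono_spike") {
      bg <- stats::rlnorm(1, log(0.15), 0.4)
      tt <- sample(tissues, 1L)
      E[i, ] <- bg
      E[i, tt] <- bg * spec$mono_fold
      spike_tissues[i] <- tt
      spike_fold[i] <- spec$mono_fold
    } else if (a == "poly_spike") {
      bg <- stats::rlnorm(1, log(0.15), 0.4)
      tt <- sample(tissues, spec$poly_size)
      E[i, ] <- bg
      E[i, tt] <- bg * spec$poly_fold
      spike_tissues[i] <- paste(tt, collapse = ";")
      spike_fold[i] <- spec$poly_fold
    } else if (a == "co_regulated") {
      pr <- sort(c(gid[i], partner[i]))
      key <- paste(pr, collapse = "|")
      if (is.null(latent[[key]])) latent[[key]] <- stats::rnorm(spec$n_tissues)
      base <- stats::rlnorm(1, log(5), 0.5)
      E[i, ] <- base * exp(spec$latent_strength * latent[[key]] +
                             stats::rnorm(spec$n_tissues, 0, 0.1))
    } else {  # uniform and sex_biased share a flat profile
      base <- if (genes$biotype_class[i] %in% c("pcg", "lncRNA")) {
        stats::rlnorm(1, log(50), 1)
      } else {
        stats::rlnorm(1, log(1), 0.5)
      }
      E[i, ] <- base
      if (a == "sex_biased") sex_tissue[i] <- sample(tissues, 1L)
    }
  }

  # preserve planted absolute TPM of spiked genes; scale the rest so each
  # tissue column sums to 1e6
  spiked <- archetype %in% c("mono_spike", "poly_spike")
  for (t in seq_len(spec$n_tissues)) {
    budget <- 1e6 - sum(E[spiked, t])
    if (budget <= 0) .stopf("spiked expression exceeds the TPM budget")
    E[!spiked, t] <- E[!spiked, t] * budget / sum(E[!spiked, t])
  }

  counts <- matrix(0L, nrow = n_g, ncol = nrow(sheet),
                   dimnames = list(gid, sheet$sample_id))
  lib <- round(stats::rlnorm(nrow(sheet), log(spec$libsize), spec$libsize_sdlog))
  t_of <- match(sheet$tissue, tissues)
  for (s in seq_len(nrow(sheet))) {
    e <- E[, t_of[s]]
    if (sheet$sex[s] == "M") {
      male_boost <- sex_tissue != "" & sex_tissue == sheet$tissue[s]
      e[male_boost] <- e[male_boost] * 2^spec$sex_log2fc
    }
    w <- e * lengths
    mu <- lib[s] * w / sum(w)
    counts[, s] <- stats::rnbinom(n_g, mu = mu, size = 1 / spec$dispersion)
  }

  truth <- data.frame(gene_id = gid, biotype_class = genes$biotype_class,
                      archetype = archetype, spike_tissues = spike_tissues,
                      fold = spike_fold, sex_tissue = sex_tissue,
                      sex_log2fc = ifelse(sex_tissue == "", NA_real_, spec$sex_log2fc),
                      partner = partner, stringsAsFactors = FALSE)
  list(counts = counts, lengths = lengths, samples = sheet,
       truth = .reset_rownames(truth), expected_tpm = E)
}
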