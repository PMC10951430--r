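# Pipeline orchestration: build -> quantify -> tau -> classify -> coexpr,
# driven by a single YAML config in which every threshold is a named key,
# and the consolidated per-gene annotation table.

.default_params <- function() {
  list(min_expr = 0.1, min_reads = 6, min_frac = 0.5,
       sex_min_frac = 0.8, sex_min_per_sex = 8,
       tau_threshold = 0.90, ts_min_expr = 1, gap_fc = 2,
       window_classify = 1e5, window_coexpr = 1e6,
       min_abs_tau = 0.55, fdr = 0.05, cage_slop = 30,
       same_class_only = TRUE, seed = 1)
}

#' Run the full atlas pipeline from a config
#'
#' Stages run in dependency order: source loading (GTF paths, or the
#' synthetic fixture generator when the config carries a `fixtures`
#' block), merging, optional CAGE support scoring, expression
#' quantification (TPM, TMM, per-tissue medians, expressed flags), tau
#' specificity, positional classification plus miRNA hosts, co-expression
#' calling, and the consolidated annotation table. Each stage's table is
#' written under `out_dir`; a JSON manifest records parameters and seed
#' (no timestamps, so reruns with the same config are byte-identical).
#' Configs without expression inputs stop after the build stage and leave
#' the downstream columns `NA`.
#'
#' @param config Path to a YAML file or an equivalent named list. Keys:
#'   `sources` (list of `name`/`path`/`priority`) or `fixtures` (arguments
#'   for [fixture_spec()]); optional `cage` (BED path); optional `counts`,
#'   `lengths`, `samples` (TSV paths) for expression when not using
#'   fixtures; `params` overriding any default threshold.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  params <- utils::modifyList(.default_params(), cfg$params %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs -------------------------------------------------------------
  fixture <- NULL
  if (!is.null(cfg$fixtures)) {
    spec <- do.call(fixture_spec, cfg$fixtures)
    fixture <- generate_annotations(spec)
    sources <- fixture$sources
  } else if (!is.null(cfg$sources)) {
    for (s in cfg$sources) {
      if (is.null(s$path) || !file.exists(s$path)) {
        .stopf("missing annotation input: %s", s$path %||% "<unnamed>")
      }
    }
    sources <- lapply(cfg$sources, function(s) {
      read_gtf(s$path, s$name, priority = s$priority %||% 1L)
    })
  } else {
    .stopf("config needs either a 'sources' or a 'fixtures' block")
  }
  for (key in c("counts", "lengths", "samples")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      .stopf("missing expression input: %s", cfg[[key]])
    }
  }

  # ---- build --------------------------------------------------------------
  atlas <- merge_annotations(sources, same_class_only = isTRUE(params$same_class_only))
  write_gtf(atlas, file.path(out_dir, "atlas.gtf"))
  .write_tsv(atlas$rejections, file.path(out_dir, "rejections.tsv"))
  .write_tsv(atlas$xref, file.path(out_dir, "xref.tsv"))

  cage <- NULL
  if (!is.null(cfg$cage)) {
    cage <- read_cage_bed(cfg$cage, slop = params$cage_slop)
    supp <- cage_support(as_annotation_source(atlas), cage)
    .write_tsv(data.frame(biotype_class = names(supp), frac_supported = as.numeric(supp)),
               file.path(out_dir, "cage_support.tsv"))
  }

  # ---- expression ---------------------------------------------------------
  expr <- NULL
  if (!is.null(fixture)) {
    expr <- generate_expression(do.call(fixture_spec, cfg$fixtures), atlas)
  } else if (!is.null(cfg$counts)) {
    counts <- as.matrix(utils::read.delim(cfg$counts, row.names = 1, check.names = FALSE))
    lens <- utils::read.delim(cfg$lengths)
    lengths <- stats::setNames(lens[[2]], lens[[1]])
    samples <- utils::read.delim(cfg$samples, stringsAsFactors = FALSE)
    expr <- list(counts = counts, lengths = lengths, samples = samples)
  }

  result <- list(atlas = atlas, params = params)
  profile <- flags <- ts <- pairs <- hosts <- coexpr <- NULL
  if (!is.null(expr)) {
    counts <- expr$counts[intersect(rownames(expr$counts), atlas$genes$gene_id), , drop = FALSE]
    lengths <- expr$lengths[rownames(counts)]
    tpm <- compute_tpm(counts, lengths)
    tmm <- tmm_expression(counts, lengths)
    profile <- tissue_medians(tpm, expr$samples)
    flags <- flag_expressed(counts, tpm, tmm, expr$samples, medians = profile,
                            min_expr = params$min_expr, min_reads = params$min_reads,
                            min_frac = params$min_frac)
    .write_tsv(data.frame(gene_id = rownames(profile), profile, check.names = FALSE),
               file.path(out_dir, "profile.tsv"))
    .write_tsv(flags, file.path(out_dir, "flags.tsv"))

    ts <- ts_table(profile, tau_threshold = params$tau_threshold,
                   min_expr = params$ts_min_expr, gap_fc = params$gap_fc)
    .write_tsv(ts, file.path(out_dir, "tau.tsv"))

    pairs_cls <- classify_genes(atlas, "lncRNA", "pcg", window = params$window_classify)
    .write_tsv(pairs_cls, file.path(out_dir, "classification.tsv"))
    hosts <- mirna_hosts(atlas)
    .write_tsv(hosts, file.path(out_dir, "mirna_hosts.tsv"))

    expressed <- stats::setNames(flags$expressed, flags$gene_id)
    pairs <- rbind(pair_for_coexpression(atlas, "lncRNA", "pcg", window = params$window_coexpr),
                   pair_for_coexpression(atlas, "pcg", "pcg", window = params$window_coexpr))
    .write_tsv(pairs, file.path(out_dir, "pairs.tsv"))
    coexpr <- call_coexpression(pairs, profile, expressed = expressed,
                                min_abs_tau = params$min_abs_tau, fdr = params$fdr)
    .write_tsv(coexpr$results, file.path(out_dir, "coexpr.tsv"))
    result <- c(result, list(profile = profile, flags = flags, ts = ts,
                             classification = pairs_cls, hosts = hosts,
                             coexpr = coexpr))
  }
  # without expression inputs the pipeline stops after the build stage;
  # downstream columns of the annotation table stay NA

  tab <- build_annotation_table(atlas, flags = flags, profile = profile, ts = ts,
                                classification = result$classification, hosts = hosts,
                                coexpr = coexpr)
  .write_tsv(tab, file.path(out_dir, "annotation_table.tsv"))
  result$annotation_table <- tab

  manifest <- list(package_version = as.character(utils::packageVersion("atlaskit")),
                   params = params,
                   sources = vapply(sources, `[[`, character(1), "name"),
                   n_genes = nrow(atlas$genes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Consolidated per-gene annotation table
#'
#' Full outer join of all stage outputs on `gene_id`: one row per atlas
#' gene; columns from stages that did not run stay `NA`. Errors on a
#' duplicated gene id in any input.
#'
#' @param atlas `merged_atlas`.
#' @param flags [flag_expressed()] output.
#' @param profile Per-tissue median matrix (adds one `tpm_<tissue>` column
#'   per tissue).
#' @param ts [ts_table()] output.
#' @param classification [classify_genes()] output (focal genes).
#' @param hosts [mirna_hosts()] output (collapsed per host gene).
#' @param coexpr [call_coexpression()] output.
#' @return data.frame with one row per atlas gene.
#' @export
build_annotation_table <- function(atlas, flags = NULL, profile = NULL, ts = NULL,
                                   classification = NULL, hosts = NULL,
                                   coexpr = NULL) {
  g <- atlas$genes
  if (anyDuplicated(g$gene_id)) .stopf("duplicate gene_id in atlas genes")
  xr <- atlas$xref
  xref_str <- tapply(paste0(xr$source, ":", xr$native_id), xr$gene_id,
                     paste, collapse = ";")
  tab <- data.frame(gene_id = g$gene_id, source = g$source,
                    xrefs = unname(xref_str[g$gene_id]),
                    biotype_class = g$biotype_class, chrom = g$chrom,
                    start = g$start, end = g$end, strand = g$strand,
                    n_transcripts = g$n_transcripts, n_exons = g$n_exons,
                    monoexonic = g$monoexonic, stringsAsFactors = FALSE)

  join <- function(tab, df, key = "gene_id") {
    if (is.null(df) || !nrow(df)) return(tab)
    if (anyDuplicated(df[[key]])) .stopf("duplicate gene_id in a stage output")
    merge(tab, df, by.x = "gene_id", by.y = key, all.x = TRUE, sort = FALSE)
  }

  tab <- join(tab, flags)
  if (!is.null(profile)) {
    pdf <- data.frame(gene_id = rownames(profile), profile, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(pdf)[-1] <- paste0("tpm_", colnames(profile))
    tab <- join(tab, pdf)
  }
  tab <- join(tab, ts)
  if (!is.null(classification)) {
    cl <- classification[, c("focal_id", "partner_id", "relation", "direction",
                             "orientation", "distance")]
    names(cl) <- c("gene_id", "closest_pcg", "pcg_relation", "pcg_direction",
                   "pcg_orientation", "pcg_distance")
    tab <- join(tab, cl)
  }
  if (!is.null(hosts) && nrow(hosts)) {
    hg <- tapply(hosts$mirna_id, hosts$host_gene_id, paste, collapse = ";")
    tab <- join(tab, data.frame(gene_id = names(hg), hosted_mirnas = unname(hg),
                                stringsAsFactors = FALSE))
  }
  if (!is.null(coexpr)) {
    r <- coexpr$results
    r <- r[order(r$focal_id, -abs(r$tau)), , drop = FALSE]
    r <- r[!duplicated(r$focal_id), c("focal_id", "partner_id", "tau", "q_value",
                                      "significant")]
    names(r) <- c("gene_id", "coexpr_partner", "coexpr_tau", "coexpr_q",
                  "coexpr_significant")
    tab <- join(tab, r)
  }
  tab <- tab[order(tab$chrom, tab$start, tab$gene_id), , drop = FALSE]
  if (nrow(tab) != nrow(g)) .stopf("annotation table row count drifted from atlas")
  .reset_rownames(tab)
}
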