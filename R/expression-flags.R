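# Per-tissue median profiles and the expressed-gene rules.

.validate_sample_table <- function(samples, require_sex = FALSE) {
  need <- c("sample_id", "tissue", "project")
  if (require_sex) need <- c(need, "sex")
  miss <- setdiff(need, names(samples))
  if (length(miss)) .stopf("sample table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) .stopf("duplicate sample_id in sample table")
  if (any(is.na(samples$tissue)) || any(is.na(samples$project))) {
    .stopf("every sample needs a tissue and a project")
  }
  invisible(samples)
}

#' Per-tissue median expression profiles (median of project medians)
#'
#' Stage 1: within each (tissue, project) group, the per-gene median TPM
#' over that group's samples. Stage 2: for tissues covered by several
#' projects, the median over the stage-1 project medians; single-project
#' tissues pass through stage 1 unchanged. The result is therefore
#' invariant to sample order and to duplicating a project's whole sample
#' set, and an unbalanced design contributes one value per project
#' regardless of its sample count.
#'
#' @param tpm TPM matrix, genes x samples (column names = sample ids).
#' @param samples Sample sheet data.frame with `sample_id`, `tissue`,
#'   `project` (and optionally `sex`).
#' @return Matrix genes x tissues of median TPM, tissues in sorted order.
#' @export
tissue_medians <- function(tpm, samples) {
  .validate_sample_table(samples)
  tpm <- as.matrix(tpm)
  if (!all(samples$sample_id %in% colnames(tpm))) {
    .stopf("sample sheet lists samples absent from the expression matrix")
  }
  groups <- split(samples$sample_id, paste(samples$tissue, samples$project, sep = "\r"))
  stage1 <- vapply(groups, function(ids) {
    apply(tpm[, ids, drop = FALSE], 1, stats::median)
  }, numeric(nrow(tpm)))
  if (nrow(tpm) == 1L) stage1 <- matrix(stage1, nrow = 1L, dimnames = list(rownames(tpm), names(groups)))
  tiss_of <- vapply(strsplit(names(groups), "\r", fixed = TRUE), `[[`, character(1), 1)
  tissues <- sort(unique(tiss_of))
  out <- vapply(tissues, function(tt) {
    cols <- which(tiss_of == tt)
    apply(stage1[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(tpm)))
  if (nrow(tpm) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(tpm), tissues))
  rownames(out) <- rownames(tpm)
  out
}

#' Expressed-gene calling and expression categories
#'
#' A gene is called expressed when both hold:
#' \enumerate{
#'   \item its median TPM is at least `min_expr` in at least one tissue, and
#'   \item in at least one (tissue, project) group, at least `min_frac` of
#'     the group's samples individually satisfy reads >= `min_reads`, TPM >=
#'     `min_expr` and TMM expression >= `min_expr`.
#' }
#' With `same_tissue = TRUE` the group of clause 2 must belong to a tissue
#' whose median already satisfies clause 1 (the stricter reading of the
#' rule); the default combines the two clauses as independent existentials.
#' The expression category comes from the maximum tissue median:
#' `lt_0.1` (< 0.1 TPM everywhere), `from_0.1_to_1` (in `[0.1, 1)` in the
#' best tissue) or `ge_1` (>= 1 TPM somewhere).
#'
#' @param counts,tpm,tmm Matrices genes x samples (raw counts, TPM, TMM
#'   expression), identical dimnames.
#' @param samples Sample sheet (`sample_id`, `tissue`, `project`).
#' @param medians Optional precomputed [tissue_medians()] matrix.
#' @param min_expr Expression floor, default 0.1.
#' @param min_reads Per-sample read floor, default 6.
#' @param min_frac Fraction of a group's samples that must pass, default 0.5.
#' @param same_tissue Couple the two clauses to the same tissue.
#' @return data.frame `gene_id`, `expressed`, `category`, `max_median`.
#' @export
flag_expressed <- function(counts, tpm, tmm, samples,
                           medians = tissue_medians(tpm, samples),
                           min_expr = 0.1, min_reads = 6, min_frac = 0.5,
                           same_tissue = FALSE) {
  .validate_sample_table(samples)
  counts <- as.matrix(counts); tpm <- as.matrix(tpm); tmm <- as.matrix(tmm)
  pass <- counts >= min_reads & tpm >= min_expr & tmm >= min_expr

  keys <- paste(samples$tissue, samples$project, sep = "\r")
  groups <- split(samples$sample_id, keys)
  frac <- vapply(groups, function(ids) {
    rowMeans(pass[, ids, drop = FALSE])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) frac <- matrix(frac, nrow = 1L, dimnames = list(rownames(counts), names(groups)))
  group_ok <- frac >= min_frac

  med_ok <- medians >= min_expr
  clause1 <- apply(med_ok, 1, any)

  if (same_tissue) {
    tiss_of <- vapply(strsplit(colnames(group_ok), "\r", fixed = TRUE), `[[`, character(1), 1)
    tissue_pass <- med_ok[, tiss_of, drop = FALSE]
    clause2 <- apply(group_ok & tissue_pass, 1, any)
  } else {
    clause2 <- apply(group_ok, 1, any)
  }

  max_med <- apply(medians, 1, max)
  category <- cut(max_med, breaks = c(-Inf, min_expr, 1, Inf), right = FALSE,
                  labels = c("lt_0.1", "from_0.1_to_1", "ge_1"))
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             expressed = unname(clause1 & clause2),
             category = as.character(category),
             max_median = unname(max_med),
             stringsAsFactors = FALSE)
}

#' Per-sex expressed-gene filter for one (tissue, project)
#'
#' The eligibility rule requires at least `min_per_sex` individuals of each
#' sex in the chosen tissue/project; the gene passes when, for at least one
#' sex, at least `min_frac` (default 80%) of that sex's samples satisfy
#' reads >= `min_reads`, TPM >= `min_expr` and TMM expression >= `min_expr`.
#'
#' @inheritParams flag_expressed
#' @param tissue,project The group to evaluate.
#' @param min_frac Default 0.8.
#' @param min_per_sex Minimum individuals per sex, default 8.
#' @return Named logical vector over genes.
#' @export
flag_expressed_per_sex <- function(counts, tpm, tmm, samples, tissue, project,
                                   min_expr = 0.1, min_reads = 6,
                                   min_frac = 0.8, min_per_sex = 8) {
  .validate_sample_table(samples, require_sex = TRUE)
  sub <- samples[samples$tissue == tissue & samples$project == project, , drop = FALSE]
  n_by_sex <- c(M = sum(sub$sex == "M"), F = sum(sub$sex == "F"))
  if (any(n_by_sex < min_per_sex)) {
    .stopf("tissue %s / project %s has %d M and %d F samples; need >= %d per sex",
           tissue, project, n_by_sex[["M"]], n_by_sex[["F"]], min_per_sex)
  }
  counts <- as.matrix(counts); tpm <- as.matrix(tpm); tmm <- as.matrix(tmm)
  pass <- counts >= min_reads & tpm >= min_expr & tmm >= min_expr
  ok <- rep(FALSE, nrow(counts))
  for (sx in c("M", "F")) {
    ids <- sub$sample_id[sub$sex == sx]
    ok <- ok | rowMeans(pass[, ids, drop = FALSE]) >= min_frac
  }
  stats::setNames(ok, rownames(counts))
}
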