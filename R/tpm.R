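# Within-sample expression normalization.

#' Transcripts-per-million from raw counts
#'
#' `TPM[g, s] = 1e6 * (count[g, s] / length[g]) / sum_g(count[g, s] /
#' length[g])`. Columns of an all-zero sample stay zero and the sample ids
#' are recorded in the `"zero_samples"` attribute (with a warning).
#'
#' @param counts Numeric matrix, genes x samples, non-negative. Row names
#'   are gene ids.
#' @param lengths Numeric vector of gene lengths in bp, recycled against
#'   `counts` rows (named vectors are matched by row name).
#' @return TPM matrix of the same dimensions; columns sum to 1e6 (or 0 for
#'   all-zero samples).
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) .stopf("lengths must match count rows")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) .stopf("gene lengths must be > 0")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  tot[zero] <- 1  # keep the division defined; those columns are all zero anyway
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  if (any(zero)) {
    ids <- colnames(counts)[zero] %||% which(zero)
    .warnf("sample(s) with zero total counts: %s", paste(ids, collapse = ", "))
    attr(tpm, "zero_samples") <- ids
  }
  tpm
}
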