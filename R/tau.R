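# Tau tissue-specificity and the gap-based specificity categories.

#' Tau tissue-specificity index
#'
#' On the transformed per-tissue medians `x_t` (default `log10(x + 1)`, so
#' zero-expression tissues contribute 0 and tau stays in `[0, 1]`):
#' `x_hat_t = x_t / max_t(x_t)` and `tau = sum_t(1 - x_hat_t) / (T - 1)`.
#' Tau is 0 for a perfectly uniform profile and 1 for expression confined
#' to a single tissue. An all-zero profile has no defined tau and returns
#' `NA` with a warning.
#'
#' @param x Numeric vector of per-tissue median expression (>= 0), or a
#'   matrix genes x tissues (tau computed per row).
#' @param transform Monotone transform applied to the medians before
#'   normalization; default `log10(x + 1)`.
#' @return Numeric tau (vector for matrix input).
#' @examples
#' compute_tau(c(10, 0, 0))          # 1: single-tissue expression
#' compute_tau(c(5, 5, 5))           # 0: uniform
#' @export
compute_tau <- function(x, transform = function(v) log10(v + 1)) {
  if (is.matrix(x)) {
    return(apply(x, 1, compute_tau, transform = transform))
  }
  if (length(x) < 2L) .stopf("tau needs at least two tissues")
  if (any(x < 0)) .stopf("tau is defined for non-negative expression values")
  tx <- transform(x)
  mx <- max(tx)
  if (mx <= 0) {
    .warnf("all-zero expression profile: tau undefined")
    return(NA_real_)
  }
  sum(1 - tx / mx) / (length(x) - 1L)
}

#' Tissue-specificity call and category for one gene
#'
#' A gene is tissue-specific (TS) when `tau >= tau_threshold` (default
#' 0.90) and its best tissue median reaches `min_expr` (default 1 TPM).
#' TS genes are then categorized by scanning the medians in descending
#' order (ties broken by tissue name) for the first consecutive pair with
#' fold-change `>= gap_fc` (default 2; a zero denominator counts as a
#' gap): a gap after position 1 gives `mono_TS`, after positions 2..7
#' `poly2to7_TS`, and a later or absent gap the residual `poly8to47_TS`.
#' The tissues before the gap form `specific_tissues` (all tissues when no
#' gap is found).
#'
#' @param medians Named numeric vector of per-tissue median TPM.
#' @param tau Tau for this profile; computed from `medians` by default.
#' @param tau_threshold TS threshold on tau, default 0.90.
#' @param min_expr Expression floor on the best tissue, default 1 TPM.
#' @param gap_fc Fold-change defining a gap, default 2.
#' @param mono_max,poly_max Category boundaries (1 and 7).
#' @return Object of class `tau_result`: list with `tau`, `n_tissues`,
#'   `ts_flag`, `ts_category` (`mono_TS`, `poly2to7_TS`, `poly8to47_TS` or
#'   `not_TS`) and `specific_tissues`.
#' @export
classify_ts <- function(medians, tau = compute_tau(medians),
                        tau_threshold = 0.90, min_expr = 1, gap_fc = 2,
                        mono_max = 1, poly_max = 7) {
  if (is.null(names(medians))) names(medians) <- paste0("tissue_", seq_along(medians))
  ts_flag <- !is.na(tau) && tau >= tau_threshold
  res <- list(tau = tau, n_tissues = length(medians), ts_flag = ts_flag,
              ts_category = "not_TS", specific_tissues = character(0))
  class(res) <- "tau_result"
  if (!ts_flag || max(medians) < min_expr) return(res)

  ord <- order(-medians, names(medians))
  m <- medians[ord]
  k <- NA_integer_
  for (i in seq_len(length(m) - 1L)) {
    gap <- if (m[i + 1L] == 0) m[i] > 0 else (m[i] / m[i + 1L]) >= gap_fc
    if (gap) { k <- i; break }
  }
  if (is.na(k)) {
    res$ts_category <- "poly8to47_TS"
    res$specific_tissues <- names(m)
  } else {
    res$specific_tissues <- names(m)[seq_len(k)]
    res$ts_category <- if (k <= mono_max) "mono_TS"
      else if (k <= poly_max) "poly2to7_TS"
      else "poly8to47_TS"
  }
  res
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("<tau_result> tau = %.3f over %d tissues: %s\n",
              x$tau, x$n_tissues, x$ts_category))
  if (length(x$specific_tissues) && x$ts_category %in% c("mono_TS", "poly2to7_TS")) {
    cat("  specific to:", paste(x$specific_tissues, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tissue-specificity table for a whole profile matrix
#'
#' Applies [compute_tau()] and [classify_ts()] to every row of a per-tissue
#' median matrix.
#'
#' @param profile Matrix genes x tissues of median TPM.
#' @param ... Passed to [classify_ts()].
#' @return data.frame `gene_id`, `tau`, `ts_flag`, `ts_category`,
#'   `n_specific`, `specific_tissues` (semicolon-joined).
#' @export
ts_table <- function(profile, ...) {
  profile <- as.matrix(profile)
  rows <- lapply(seq_len(nrow(profile)), function(i) {
    m <- profile[i, ]
    tau <- suppressWarnings(compute_tau(m))
    r <- classify_ts(m, tau = tau, ...)
    data.frame(gene_id = rownames(profile)[i] %||% as.character(i),
               tau = r$tau, ts_flag = r$ts_flag, ts_category = r$ts_category,
               n_specific = length(r$specific_tissues),
               specific_tissues = paste(r$specific_tissues, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  .reset_rownames(do.call(rbind, rows))
}

#' Census of tissue-specific genes
#'
#' Counts TS genes per (biotype class, category) and, attributing each gene
#' to every tissue in its specific group, per (tissue, category).
#'
#' @param ts A [ts_table()] data.frame.
#' @param classes Named character vector mapping gene_id to biotype class
#'   (optional; genes missing from it are counted under `"all"`).
#' @return List with `by_class` (data.frame `biotype_class`, `ts_category`,
#'   `n`) and `by_tissue` (data.frame `tissue`, `ts_category`, `n`).
#' @export
ts_census <- function(ts, classes = NULL) {
  cls <- if (is.null(classes)) rep("all", nrow(ts)) else {
    out <- unname(classes[ts$gene_id])
    out[is.na(out)] <- "all"
    out
  }
  keep <- ts$ts_category != "not_TS"
  by_class <- as.data.frame(table(biotype_class = cls[keep],
                                  ts_category = ts$ts_category[keep]),
                            responseName = "n", stringsAsFactors = FALSE)
  by_class <- by_class[by_class$n > 0 | TRUE, , drop = FALSE]

  tl <- strsplit(ts$specific_tissues[keep], ";", fixed = TRUE)
  cat_rep <- rep(ts$ts_category[keep], lengths(tl))
  by_tissue <- as.data.frame(table(tissue = unlist(tl), ts_category = cat_rep),
                             responseName = "n", stringsAsFactors = FALSE)
  list(by_class = .reset_rownames(by_class), by_tissue = .reset_rownames(by_tissue))
}
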