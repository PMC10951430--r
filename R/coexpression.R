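# Kendall rank correlation of paired expression profiles across tissues,
# Benjamini-Hochberg control within pair-type batches, and the
# co-expression significance rule (|tau| >= 0.55 and q <= 0.05).

#' Kendall tau-b with p-value
#'
#' Tie-corrected tau-b. The p-value comes from exact enumeration of all
#' permutations of one vector for `n <= 8` (the default `exact` rule) and
#' otherwise from the normal approximation with the tie-adjusted variance
#' of the S statistic. Constant input vectors have no defined correlation
#' and yield `NA` for both fields.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param exact Use exact permutation enumeration for the p-value; defaults
#'   to `length(x) <= 8`.
#' @return List with `tau` and `p_value`.
#' @examples
#' kendall_tau(1:3, c(1, 2, 3))$tau   #  1
#' kendall_tau(1:3, c(3, 2, 1))$tau   # -1
#' @export
kendall_tau <- function(x, y, exact = length(x) <= 8) {
  if (length(x) != length(y)) .stopf("x and y must have the same length")
  n <- length(x)
  if (n < 3L) .stopf("kendall_tau needs n >= 3")
  if (anyNA(x) || anyNA(y)) .stopf("missing values not allowed")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(tau = NA_real_, p_value = NA_real_))
  }

  ij <- utils::combn(n, 2L)
  dx <- sign(x[ij[1, ]] - x[ij[2, ]])
  dy <- sign(y[ij[1, ]] - y[ij[2, ]])
  S <- sum(dx * dy)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  p <- if (exact) .kendall_exact_p(x, y, dx, ij, S) else .kendall_normal_p(x, y, S)
  list(tau = tau, p_value = p)
}

# all-permutations null distribution of S (feasible for n <= 8)
.kendall_exact_p <- function(x, y, dx, ij, S) {
  n <- length(x)
  P <- .permutations(n)
  Y <- matrix(y[P], nrow = nrow(P))
  D <- sign(Y[, ij[1, ], drop = FALSE] - Y[, ij[2, ], drop = FALSE])
  S_perm <- as.numeric(D %*% dx)
  mean(abs(S_perm) >= abs(S) - 1e-9)
}

.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (n == 1L) matrix(1L) else {
    sub <- .permutations(n - 1L)
    out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
    for (k in seq_len(n)) {
      rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
      out[rows, 1L] <- k
      rest <- seq_len(n)[-k]
      out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
    }
    out
  }
  .perm_cache[[key]] <- res
  res
}

# normal approximation with the tie-adjusted variance of S
.kendall_normal_p <- function(x, y, S) {
  n <- length(x)
  tx <- as.numeric(table(x)); ty <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) return(NA_real_)
  # continuity correction (half the lattice spacing of S), clamped at 1
  min(1, 2 * stats::pnorm(-max(0, abs(S) - 1) / sqrt(var_s)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} (m * p_(j) / j)`, returned in
#' the input order. Monotone in p and never below the raw p-value.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @return Vector of adjusted q-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call significant co-expression for gene pairs
#'
#' For each pair, Kendall tau-b between the two genes' per-tissue median
#' expression vectors; BH adjustment is applied within each `pair_type`
#' batch; a pair is significant when `|tau| >= min_abs_tau` and
#' `q <= fdr`. Pairs whose genes lack a profile (or, when `expressed` is
#' supplied, are not flagged expressed) are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param pairs data.frame from [pair_for_coexpression()] (columns
#'   `focal_id`, `partner_id`, `pair_type`; optionally `configuration`,
#'   `distance`).
#' @param profile Matrix genes x tissues of median TPM.
#' @param expressed Optional named logical vector of expressed flags; both
#'   genes of a pair must be `TRUE`.
#' @param min_abs_tau Significance threshold on `|tau|`, default 0.55.
#' @param fdr BH false-discovery-rate threshold, default 0.05.
#' @param dist_break Distance stratum boundary in bp for the summary,
#'   default 5 kb.
#' @return Object of class `coexpression_calls`: list with `results`
#'   (per-pair data.frame adding `tau`, `p_value`, `q_value`,
#'   `significant`) and `summary` (fraction significant per configuration
#'   and per distance stratum for intergenic pairs).
#' @export
call_coexpression <- function(pairs, profile, expressed = NULL,
                              min_abs_tau = 0.55, fdr = 0.05,
                              dist_break = 5000) {
  profile <- as.matrix(profile)
  keep <- pairs$focal_id %in% rownames(profile) & pairs$partner_id %in% rownames(profile)
  if (!is.null(expressed)) {
    ex_f <- expressed[pairs$focal_id]; ex_p <- expressed[pairs$partner_id]
    keep <- keep & !is.na(ex_f) & !is.na(ex_p) & ex_f & ex_p
  }
  n_skipped <- sum(!keep)
  if (n_skipped) message(sprintf("skipping %d pair(s) without usable profiles", n_skipped))
  res <- pairs[keep, , drop = FALSE]

  kt <- lapply(seq_len(nrow(res)), function(i) {
    kendall_tau(profile[res$focal_id[i], ], profile[res$partner_id[i], ],
                exact = ncol(profile) <= 8)
  })
  res$tau <- vapply(kt, `[[`, numeric(1), "tau")
  res$p_value <- vapply(kt, `[[`, numeric(1), "p_value")
  res$q_value <- NA_real_
  for (bt in unique(res$pair_type)) {
    sel <- res$pair_type == bt
    res$q_value[sel] <- bh_adjust(res$p_value[sel])
  }
  res$significant <- !is.na(res$tau) & abs(res$tau) >= min_abs_tau &
    !is.na(res$q_value) & res$q_value <= fdr

  summ <- list()
  if (!is.null(res$configuration)) {
    summ$by_configuration <- .frac_by(res, c("pair_type", "configuration"))
  }
  if (!is.null(res$distance) && !is.null(res$relation)) {
    inter <- res[res$relation == "intergenic", , drop = FALSE]
    if (nrow(inter)) {
      inter$stratum <- ifelse(inter$distance <= dist_break,
                              sprintf("le_%dbp", as.integer(dist_break)),
                              sprintf("gt_%dbp", as.integer(dist_break)))
      summ$by_distance <- .frac_by(inter, c("pair_type", "configuration", "stratum"))
    }
  }
  structure(list(results = .reset_rownames(res), summary = summ,
                 min_abs_tau = min_abs_tau, fdr = fdr),
            class = "coexpression_calls")
}

.frac_by <- function(df, by) {
  key <- do.call(paste, c(df[by], sep = "\r"))
  agg <- tapply(df$significant, key, function(v) c(n = length(v), n_sig = sum(v)))
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- by
  out$n <- vapply(agg, `[[`, numeric(1), "n")
  out$n_significant <- vapply(agg, `[[`, numeric(1), "n_sig")
  out$frac_significant <- out$n_significant / out$n
  .reset_rownames(out)
}

#' @export
print.coexpression_calls <- function(x, ...) {
  r <- x$results
  cat(sprintf("<coexpression_calls> %d pairs, %d significant (|tau| >= %.2f, q <= %.2f)\n",
              nrow(r), sum(r$significant), x$min_abs_tau, x$fdr))
  invisible(x)
}
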