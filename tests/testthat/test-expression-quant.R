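# TPM, TMM factors and expression, tissue medians, expressed-gene rules.

test_that("TPM follows the length-normalized definition", {
  expect_equal(as.numeric(compute_tpm(matrix(5, 1, 1), 1000)), 1e6)
  tpm <- compute_tpm(matrix(c(10, 10), 2, 1), c(1000, 2000))
  expect_equal(as.numeric(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(501)
  counts <- matrix(rpois(200, 40), 20, 10)
  tpm <- compute_tpm(counts, runif(20, 200, 5000))
  expect_equal(unname(colSums(tpm)), rep(1e6, 10))
  # depth invariance: scaling a sample's counts leaves its TPM unchanged
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 7L
  expect_equal(compute_tpm(counts2, rep(1000, 20))[, 3],
               compute_tpm(counts, rep(1000, 20))[, 3])
  expect_error(compute_tpm(counts, c(0, rep(1000, 19))), "> 0")
  expect_warning(compute_tpm(cbind(counts[, 1], 0L), rep(1000, 20)), "zero total")
})

test_that("TMM factors are exactly 1 without composition bias", {
  set.seed(502)
  lib <- rpois(100, 50)
  expect_equal(unname(tmm_factors(cbind(lib, lib, lib))), rep(1, 3))
  # a pure depth difference has all M-values zero
  expect_equal(unname(tmm_factors(cbind(lib, 2L * lib))), c(1, 1))
})

test_that("TMM factors match the independent reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(503)
  for (rep in 1:3) {
    counts <- matrix(rnbinom(200 * 3, mu = 60 * rexp(200), size = 3), 200, 3)
    counts[sample(200, 10), 2] <- counts[sample(200, 10), 2] + 5000L
    ref <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
    expect_equal(unname(tmm_factors(counts)), ref, tolerance = 1e-6)
  }
})

test_that("TMM factors are permutation-equivariant with geometric mean 1", {
  set.seed(504)
  counts <- matrix(rnbinom(150 * 4, mu = 80, size = 2), 150, 4)
  f <- tmm_factors(counts)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(tmm_factors(counts[, perm])), unname(f[perm]), tolerance = 1e-12)
})

test_that("TMM expression is per-kb on the effective library size", {
  # count 100, length 1000 bp, library 1e6, factor 1 -> 100.0
  m <- matrix(c(100, 999900), 2, 1)
  expect_equal(tmm_expression(m, c(1000, 1000), factors = 1)[1, 1], 100)
  # doubling the factor halves the value
  expect_equal(tmm_expression(m, c(1000, 1000), factors = 2),
               tmm_expression(m, c(1000, 1000), factors = 1) / 2)
  # with all factors 1 it is plain FPKM
  set.seed(505)
  counts <- matrix(rpois(60, 30), 20, 3)
  lens <- runif(20, 500, 3000)
  fpkm <- 1e9 * sweep(counts / lens, 2, colSums(counts), "/")
  expect_equal(tmm_expression(counts, lens, factors = rep(1, 3)), fpkm)
})

test_that("tissue medians take the median of project medians", {
  tpm <- matrix(c(1, 3, 5), 1, 3, dimnames = list("g", c("a", "b", "c")))
  sheet <- data.frame(sample_id = c("a", "b", "c"), tissue = "liver", project = "p1")
  expect_equal(as.numeric(tissue_medians(tpm, sheet)), 3)

  # two projects with medians 2 and 6 -> 4
  tpm2 <- matrix(c(1, 3, 5, 7), 1, 4, dimnames = list("g", letters[1:4]))
  sheet2 <- data.frame(sample_id = letters[1:4], tissue = "liver",
                       project = c("p1", "p1", "p2", "p2"))
  expect_equal(as.numeric(tissue_medians(tpm2, sheet2)), 4)

  # unbalanced design: only the two project medians matter
  tpm3 <- matrix(c(rep(2, 10), 6, 6), 1, 12, dimnames = list("g", paste0("s", 1:12)))
  sheet3 <- data.frame(sample_id = paste0("s", 1:12), tissue = "liver",
                       project = rep(c("p1", "p2"), c(10, 2)))
  expect_equal(as.numeric(tissue_medians(tpm3, sheet3)), 4)

  # invariant to sample order and to duplicating a project wholesale
  set.seed(506)
  tpm4 <- matrix(runif(5 * 8, 0, 50), 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  sheet4 <- data.frame(sample_id = paste0("s", 1:8),
                       tissue = rep(c("liver", "brain"), each = 4),
                       project = rep(c("p1", "p2"), 4))
  base <- tissue_medians(tpm4, sheet4)
  shuf <- sheet4[sample(8), ]
  expect_equal(tissue_medians(tpm4, shuf), base)
  dup <- tpm4[, sheet4$sample_id[sheet4$project == "p1"], drop = FALSE]
  colnames(dup) <- paste0(colnames(dup), "_dup")
  sheet_dup <- sheet4[sheet4$project == "p1", ]
  sheet_dup$sample_id <- paste0(sheet_dup$sample_id, "_dup")
  expect_equal(tissue_medians(cbind(tpm4, dup), rbind(sheet4, sheet_dup)), base)
})

# one gene, one tissue, one project with four samples; helper returning the
# three layers the rule needs
rule_case <- function(counts, tpm_val, tmm_val) {
  n <- length(counts)
  sheet <- data.frame(sample_id = paste0("s", seq_len(n)), tissue = "liver",
                      project = "p1")
  list(counts = matrix(counts, 1, dimnames = list("g", sheet$sample_id)),
       tpm = matrix(tpm_val, 1, n, dimnames = list("g", sheet$sample_id)),
       tmm = matrix(tmm_val, 1, n, dimnames = list("g", sheet$sample_id)),
       sheet = sheet)
}

test_that("the expressed rule combines the median and per-sample clauses", {
  # all-zero gene: not expressed, lowest category
  z <- rule_case(rep(0, 4), rep(0, 4), rep(0, 4))
  fz <- flag_expressed(z$counts, z$tpm, z$tmm, z$sheet)
  expect_false(fz$expressed)
  expect_equal(fz$category, "lt_0.1")

  # median 0.5 TPM, 3/4 samples pass the (reads, TPM, TMM) triple
  a <- rule_case(c(10, 10, 10, 0), c(0.5, 0.5, 0.5, 0), c(0.5, 0.5, 0.5, 0))
  fa <- flag_expressed(a$counts, a$tpm, a$tmm, a$sheet)
  expect_true(fa$expressed)
  expect_equal(fa$category, "from_0.1_to_1")

  # median 5 TPM but only 1/4 samples pass: second clause fails
  b <- rule_case(c(10, 2, 2, 2), c(5, 5, 5, 5), c(5, 0.01, 0.01, 0.01))
  fb <- flag_expressed(b$counts, b$tpm, b$tmm, b$sheet)
  expect_false(fb$expressed)
  expect_equal(fb$category, "ge_1")
})

test_that("expressed is monotone in counts", {
  set.seed(507)
  sheet <- data.frame(sample_id = paste0("s", 1:8),
                      tissue = rep(c("liver", "brain"), each = 4),
                      project = "p1")
  for (rep in 1:20) {
    counts <- matrix(rpois(5 * 8, 4), 5, 8, dimnames = list(paste0("g", 1:5), sheet$sample_id))
    lens <- rep(1000, 5)
    tpm <- compute_tpm(counts, lens)
    tmm <- tmm_expression(counts, lens, factors = rep(1, 8))
    f0 <- flag_expressed(counts, tpm, tmm, sheet)
    up <- counts
    r <- sample(5, 1)
    up[r, ] <- up[r, ] + sample(0:20, 8, replace = TRUE)
    f1 <- flag_expressed(up, compute_tpm(up, lens),
                         tmm_expression(up, lens, factors = rep(1, 8)), sheet)
    raised <- rowSums(up) > rowSums(counts)
    expect_true(all(!f0$expressed[raised] | f1$expressed[raised]))
  }
})

test_that("the per-sex filter needs 80% of one sex's samples and 8 birds per sex", {
  sheet <- data.frame(sample_id = paste0("s", 1:16), tissue = "liver", project = "p1",
                      sex = rep(c("M", "F"), each = 8))
  mk <- function(male_pass, female_pass) {
    v <- c(rep(10, male_pass), rep(0, 8 - male_pass),
           rep(10, female_pass), rep(0, 8 - female_pass))
    m <- matrix(v, 1, 16, dimnames = list("g", sheet$sample_id))
    list(counts = m, tpm = m / 10, tmm = m / 10)
  }
  x <- mk(8, 0)
  expect_true(flag_expressed_per_sex(x$counts, x$tpm, x$tmm, sheet, "liver", "p1")[["g"]])
  x <- mk(6, 6)  # 75% in each sex: below the 80% bar
  expect_false(flag_expressed_per_sex(x$counts, x$tpm, x$tmm, sheet, "liver", "p1")[["g"]])
  x <- mk(8, 8)
  expect_true(flag_expressed_per_sex(x$counts, x$tpm, x$tmm, sheet, "liver", "p1")[["g"]])

  small <- sheet[1:12, ]  # only 4 females
  x <- mk(8, 8)
  expect_error(
    flag_expressed_per_sex(x$counts[, 1:12, drop = FALSE], x$tpm[, 1:12, drop = FALSE],
                           x$tmm[, 1:12, drop = FALSE], small, "liver", "p1"),
    "liver")
})
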