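# Exon-overlap primitive, conflict detection, sequential merging, and the
# CAGE / overlap-rate source statistics.

ex_df <- function(chrom, strand, ...) {
  coords <- list(...)
  data.frame(chrom = chrom, strand = strand,
             start = sapply(coords, `[`, 1), end = sapply(coords, `[`, 2))
}

test_that("exon overlap implements the 1-bp same-strand rule", {
  a <- ex_df("chr1", "+", c(1, 100))
  expect_true(exons_overlap(a, a))                                   # identity
  expect_false(exons_overlap(a, ex_df("chr1", "+", c(101, 200))))    # adjacent
  expect_true(exons_overlap(a, ex_df("chr1", "+", c(100, 200))))     # 1 bp shared
  expect_false(exons_overlap(a, ex_df("chr1", "-", c(1, 100))))      # strand
  expect_false(exons_overlap(a, ex_df("chr2", "+", c(1, 100))))      # chrom
  # intron of a spans an exon of b: no exonic base shared
  a2 <- ex_df("chr1", "+", c(1, 100), c(1000, 1100))
  b2 <- ex_df("chr1", "+", c(300, 600))
  expect_false(exons_overlap(a2, b2))
})

test_that("exons_overlap agrees with the brute-force pairwise oracle", {
  set.seed(401)
  for (rep in 1:200) {
    mk <- function() {
      n <- sample(1:4, 1)
      w <- sample(50:400, n, replace = TRUE)
      gaps <- sample(1:800, n, replace = TRUE)
      s <- cumsum(gaps + c(0, w[-n]))  # sorted, pairwise disjoint
      data.frame(chrom = sample(c("chr1", "chr2"), 1, prob = c(0.9, 0.1)),
                 strand = sample(c("+", "-"), 1, prob = c(0.8, 0.2)),
                 start = s, end = s + w)
    }
    a <- mk(); b <- mk()
    expect_equal(exons_overlap(a, b), oracle_exons_overlap(a, b))
  }
})

test_that("gene_conflicts finds exactly the overlapping accepted genes", {
  acc <- make_source("acc", 1, list(
    make_gene("pcgA", "chr1", "+", "protein_coding",
              list(list(c(1000, 1200), c(5000, 5400)))),
    g1("lncB", "chr1", "+", "lncRNA", c(9000, 9500))
  ))
  # identical candidate conflicts with its twin
  cand_src <- make_source("cand", 2, list(
    g1("pcgA2", "chr1", "+", "protein_coding", c(1000, 1200)),
    g1("mir1", "chr1", "+", "miRNA", c(2000, 2080)),    # inside pcgA's intron
    g1("mir2", "chr1", "+", "miRNA", c(1100, 1180))     # inside pcgA's exon
  ))
  expect_equal(gene_conflicts("pcgA2", cand_src, acc), "pcgA")
  # intronic miRNA conflicts with nothing in either mode
  expect_equal(gene_conflicts("mir1", cand_src, acc), character(0))
  expect_equal(gene_conflicts("mir1", cand_src, acc, same_class_only = FALSE), character(0))
  # exon-nested miRNA is saved only by the class restriction
  expect_equal(gene_conflicts("mir2", cand_src, acc), character(0))
  expect_equal(gene_conflicts("mir2", cand_src, acc, same_class_only = FALSE), "pcgA")
})

test_that("merging a single source, or a source with itself, is the identity", {
  fx <- random_fixture(402, n_sources = 1, mir_in = 0, mir_ex = 0)$fx
  s <- fx$sources[[1]]
  atlas <- merge_annotations(list(s))
  expect_setequal(atlas$genes$gene_id, s$genes$gene_id)
  expect_equal(nrow(atlas$rejections), 0L)

  s2 <- annotation_source("copy", s$exons,
                          gene_biotypes = data.frame(gene_id = s$genes$gene_id,
                                                     raw_biotype = s$genes$raw_biotype),
                          priority = 2L)
  atlas2 <- merge_annotations(list(s, s2))
  expect_setequal(atlas2$genes$gene_id, s$genes$gene_id)
  expect_equal(sort(atlas2$rejections$gene_id), sort(s2$genes$gene_id))
  # merging the atlas with itself changes nothing (idempotence)
  again <- merge_annotations(list(as_annotation_source(atlas2, priority = 1),
                                  as_annotation_source(atlas2, "atlas2", priority = 2)))
  expect_setequal(again$genes$gene_id, atlas2$genes$gene_id)
})

test_that("merge output matches the sequential brute-force oracle and its invariants", {
  for (seed in c(410, 411, 412)) {
    fx <- random_fixture(seed, n_sources = 3, pcg = 15, lnc = 10)$fx
    atlas <- merge_annotations(fx$sources)
    oracle <- oracle_merge_accepted(fx$sources)
    expect_setequal(atlas$genes$gene_id, oracle$gene_id)
    # priority-1 source fully included
    expect_true(all(fx$sources[[1]]$genes$gene_id %in% atlas$genes$gene_id))
    # no same-strand same-class exon overlaps remain (exhaustive scan)
    src_atlas <- as_annotation_source(atlas)
    g <- atlas$genes
    for (i in seq_len(nrow(g) - 1L)) for (j in (i + 1L):nrow(g)) {
      if (g$biotype_class[i] != g$biotype_class[j]) next
      expect_false(oracle_genes_overlap(src_atlas, g$gene_id[i], src_atlas, g$gene_id[j]))
    }
  }
})

test_that("accepted count grows with sources and order only reshuffles duplicates", {
  fx <- random_fixture(420, n_sources = 3, pcg = 15, lnc = 10)$fx
  n_cum <- sapply(1:3, function(k) n_genes(merge_annotations(fx$sources[1:k])))
  expect_true(all(diff(n_cum) >= 0))

  rev_atlas <- merge_annotations(list(
    annotation_source(fx$sources[[2]]$name, fx$sources[[2]]$exons,
                      gene_biotypes = data.frame(gene_id = fx$sources[[2]]$genes$gene_id,
                                                 raw_biotype = fx$sources[[2]]$genes$raw_biotype),
                      priority = 1L),
    annotation_source(fx$sources[[1]]$name, fx$sources[[1]]$exons,
                      gene_biotypes = data.frame(gene_id = fx$sources[[1]]$genes$gene_id,
                                                 raw_biotype = fx$sources[[1]]$genes$raw_biotype),
                      priority = 2L)))
  src_rev <- as_annotation_source(rev_atlas)
  g <- rev_atlas$genes
  for (i in seq_len(nrow(g) - 1L)) for (j in (i + 1L):nrow(g)) {
    if (g$biotype_class[i] != g$biotype_class[j]) next
    expect_false(oracle_genes_overlap(src_rev, g$gene_id[i], src_rev, g$gene_id[j]))
  }
})

test_that("rejections are logged with their colliders and ids are cross-referenced", {
  s1 <- make_source("one", 1, list(g1("gA", "chr1", "+", "protein_coding", c(100, 900))))
  s2 <- make_source("two", 2, list(
    g1("gB", "chr1", "+", "protein_coding", c(500, 1500)),
    g1("gC", "chr2", "+", "protein_coding", c(100, 900))))
  atlas <- merge_annotations(list(s1, s2))
  expect_equal(atlas$rejections$gene_id, "gB")
  expect_equal(atlas$rejections$conflicting_ids, "gA")
  xr <- atlas$xref
  expect_true(any(xr$gene_id == "gA" & xr$relation == "overlap" & xr$native_id == "gB"))
  expect_true(any(xr$gene_id == "gA" & xr$relation == "native" & xr$native_id == "gA"))
})

test_that("duplicate gene ids across accepted sources are renamed deterministically", {
  s1 <- make_source("one", 1, list(g1("shared", "chr1", "+", "protein_coding", c(100, 900))))
  s2 <- make_source("two", 2, list(g1("shared", "chr2", "+", "protein_coding", c(100, 900))))
  expect_message(atlas <- merge_annotations(list(s1, s2)), "renamed")
  expect_setequal(atlas$genes$gene_id, c("shared", "shared__two"))
})

test_that("overlap_rate counts class genes of a overlapping b", {
  fx <- random_fixture(430, n_sources = 2, pcg = 20, lnc = 10, overlap = 0.4,
                       mir_in = 0, mir_ex = 0)
  a <- fx$fx$sources[[1]]; b <- fx$fx$sources[[2]]
  expect_equal(overlap_rate(a, a, "pcg"), 1.0)
  # planted truth: clones of b overlap a, so rate(b -> a) = clone fraction
  tt <- fx$fx$truth
  n_clone <- sum(tt$source == "source2" & tt$biotype_class == "pcg" & tt$role == "clone")
  n_pcg <- sum(tt$source == "source2" & tt$biotype_class == "pcg")
  expect_equal(overlap_rate(b, a, "pcg"), n_clone / n_pcg)
  # disjoint chromosomes
  d1 <- make_source("d1", 1, list(g1("x", "chr1", "+", "protein_coding", c(1, 100))))
  d2 <- make_source("d2", 2, list(g1("y", "chr9", "+", "protein_coding", c(1, 100))))
  expect_equal(overlap_rate(d1, d2, "pcg"), 0.0)
})

test_that("CAGE support applies the +/-30 bp rule at the boundary", {
  src <- make_source("s", 1, list(
    g1("gPlus", "chr1", "+", "protein_coding", c(1000, 2000)),   # TSS 1000
    g1("gMinus", "chr1", "-", "lncRNA", c(3000, 4000))           # TSS 4000
  ))
  expect_equal(unname(cage_support(src, cage_peaks(
    data.frame(chrom = "chr1", start = 1010, end = 1020)))["pcg"]), 1.0)
  # 1031 - 30 = 1001 > 1000: just outside
  expect_equal(unname(cage_support(src, cage_peaks(
    data.frame(chrom = "chr1", start = 1031, end = 1040)))["pcg"]), 0.0)
  expect_equal(unname(cage_support(src, cage_peaks(
    data.frame(chrom = "chr1", start = 1030, end = 1040)))["pcg"]), 1.0)
  # minus-strand TSS matched at its own coordinate, peak strand ignored
  supp <- cage_support(src, cage_peaks(
    data.frame(chrom = "chr1", start = 4020, end = 4040, strand = "+")))
  expect_equal(unname(supp["lncRNA"]), 1.0)
})

test_that("CAGE support recovers a planted support fraction", {
  genes <- lapply(1:50, function(i) {
    g1(sprintf("g%02d", i), "chr1", "+", "protein_coding",
       c(i * 10000, i * 10000 + 800))
  })
  src <- make_source("s", 1, genes)
  # plant peaks over 30 of the 50 TSSs
  peaks <- data.frame(chrom = "chr1", start = (1:30) * 10000 - 5, end = (1:30) * 10000 + 5)
  expect_equal(unname(cage_support(src, cage_peaks(peaks))["pcg"]), 0.6)
})

test_that("BED peaks are converted to 1-based inclusive on read", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t1020\tpeak1\t5\t+", path)
  cp <- read_cage_bed(path)
  expect_equal(cp$peaks$start, 1000)
  expect_equal(cp$peaks$end, 1020)
})
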