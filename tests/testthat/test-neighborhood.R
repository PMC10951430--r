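# Positional classification relative to the closest protein-coding gene,
# miRNA host tabulation, and co-expression pairing.

tx <- function(chrom, strand, ...) {
  coords <- list(...)
  data.frame(chrom = chrom, strand = strand,
             start = sapply(coords, `[`, 1), end = sapply(coords, `[`, 2))
}

test_that("transcript pairs get the FEELnc-style configuration", {
  # same strand, focal upstream of the partner's TSS: SS up at 1 kb
  r <- classify_transcript_pair(tx("chr1", "+", c(10000, 11000)),
                                tx("chr1", "+", c(12000, 15000)))
  expect_equal(r$relation, "intergenic")
  expect_equal(r$orientation, "same_strand_up")
  expect_equal(r$distance, 1000L)

  # facing TSSs: divergent
  r <- classify_transcript_pair(tx("chr1", "-", c(10000, 11000)),
                                tx("chr1", "+", c(12000, 15000)))
  expect_equal(r$orientation, "divergent")
  # facing 3' ends: convergent
  r <- classify_transcript_pair(tx("chr1", "+", c(10000, 11000)),
                                tx("chr1", "-", c(12000, 15000)))
  expect_equal(r$orientation, "convergent")
  # minus-strand partner: upstream is on its right
  r <- classify_transcript_pair(tx("chr1", "-", c(16000, 17000)),
                                tx("chr1", "-", c(12000, 15000)))
  expect_equal(r$orientation, "same_strand_up")

  # mono-exonic focal inside the partner's intron, same strand
  pcg <- tx("chr1", "+", c(12000, 12500), c(14000, 15000))
  r <- classify_transcript_pair(tx("chr1", "+", c(13000, 13200)), pcg)
  expect_equal(r$relation, "genic_intronic")
  expect_equal(r$direction, "sense")
  expect_equal(r$distance, 0L)
  # exon overlap on the other strand is still genic_exonic, antisense
  r <- classify_transcript_pair(tx("chr1", "-", c(12400, 12600)), pcg)
  expect_equal(r$relation, "genic_exonic")
  expect_equal(r$direction, "antisense")
  # different chromosome: no classification
  expect_null(classify_transcript_pair(tx("chr2", "+", c(1, 10)), pcg))
})

test_that("gene-level calls follow precedence, window, and closest-partner rules", {
  atlas <- merge_annotations(list(make_source("s", 1, list(
    make_gene("lncX", "chr1", "+", "lncRNA",
              list(list(c(13000, 13200)), list(c(19500, 19700)))),
    make_gene("pcgA", "chr1", "+", "protein_coding",
              list(list(c(12000, 12500), c(14000, 15000)))),
    g1("pcgB", "chr1", "+", "protein_coding", c(20200, 21000)),
    g1("lncFar", "chr2", "-", "lncRNA", c(1, 300))
  ))))
  cl <- classify_genes(atlas, "lncRNA", "pcg", window = 1e5)
  x <- cl[cl$focal_id == "lncX", ]
  # one transcript intronic in A beats the other 500 bp upstream of B
  expect_equal(x$partner_id, "pcgA")
  expect_equal(x$relation, "genic_intronic")
  expect_equal(x$distance, 0L)
  far <- cl[cl$focal_id == "lncFar", ]
  expect_true(is.na(far$partner_id))

  pr <- pair_for_coexpression(atlas, "lncRNA", "pcg", window = 1e6)
  expect_equal(pr$configuration[pr$focal_id == "lncX"], "genic")
})

test_that("co-expression pairing picks the closest partner inside the window", {
  atlas <- merge_annotations(list(make_source("s", 1, list(
    g1("lnc1", "chr1", "+", "lncRNA", c(100000, 101000)),
    g1("pcgNear", "chr1", "+", "protein_coding", c(111000, 112000)),  # 10 kb
    g1("pcgFar", "chr1", "+", "protein_coding", c(141000, 142000)),   # 40 kb
    g1("lncLonely", "chr2", "+", "lncRNA", c(100, 1100))
  ))))
  pr <- pair_for_coexpression(atlas, "lncRNA", "pcg", window = 1e6)
  expect_equal(pr$partner_id[pr$focal_id == "lnc1"], "pcgNear")
  expect_false("lncLonely" %in% pr$focal_id)
  expect_equal(attr(pr, "n_unpaired"), 1L)
})

test_that("gene calls equal the exhaustive transcript-pair oracle on fixtures", {
  for (seed in c(701, 702)) {
    fx <- random_fixture(seed, n_sources = 2, pcg = 15, lnc = 12)$fx
    atlas <- merge_annotations(fx$sources)
    cl <- classify_genes(atlas, "lncRNA", "pcg", window = 1e5)
    for (i in seq_len(nrow(cl))) {
      o <- oracle_classify_gene(atlas, cl$focal_id[i], "pcg", 1e5)
      if (is.null(o)) {
        expect_true(is.na(cl$partner_id[i]))
      } else {
        expect_equal(cl$partner_id[i], o$partner)
        expect_equal(cl$relation[i], o$relation)
        expect_equal(cl$distance[i], as.integer(o$distance))
      }
    }
    # genic distance 0; intergenic positive and within the window
    inter <- cl[!is.na(cl$relation) & cl$relation == "intergenic", ]
    expect_true(all(inter$distance > 0 & inter$distance <= 1e5))
    genic <- cl[!is.na(cl$relation) & cl$relation != "intergenic", ]
    expect_true(all(genic$distance == 0))
  }
})

test_that("swapping focal and partner roles mirrors up/down and fixes div/conv", {
  set.seed(703)
  for (rep in 1:100) {
    mk <- function() {
      s <- sample(1:50000, 1)
      tx(chrom = "chr1", strand = sample(c("+", "-"), 1), c(s, s + sample(200:2000, 1)))
    }
    a <- mk(); b <- mk()
    r1 <- classify_transcript_pair(a, b)
    r2 <- classify_transcript_pair(b, a)
    if (r1$relation == "intergenic") {
      map <- c(same_strand_up = "same_strand_down", same_strand_down = "same_strand_up",
               divergent = "divergent", convergent = "convergent")
      expect_equal(r2$orientation, unname(map[r1$orientation]))
      expect_equal(r1$distance, r2$distance)
    } else {
      expect_equal(r1$relation, r2$relation)
    }
  }
})

test_that("miRNA hosts are tabulated with exon/intron relation and smallest host", {
  atlas <- merge_annotations(list(make_source("s", 1, list(
    make_gene("pcgHost", "chr1", "+", "protein_coding",
              list(list(c(1000, 1500), c(8000, 9000)))),
    g1("lncHost", "chr1", "-", "lncRNA", c(20000, 21000)),
    g1("mirIntron", "chr1", "+", "miRNA", c(2000, 2090)),
    g1("mirExon", "chr1", "-", "miRNA", c(20100, 20190)),
    g1("mirLonely", "chr2", "+", "miRNA", c(500, 590))
  ))))
  h <- mirna_hosts(atlas)
  expect_equal(nrow(h), 2L)
  expect_equal(h$host_gene_id[h$mirna_id == "mirIntron"], "pcgHost")
  expect_equal(h$relation[h$mirna_id == "mirIntron"], "intronic")
  expect_equal(h$host_class[h$mirna_id == "mirExon"], "lncRNA")
  expect_equal(h$relation[h$mirna_id == "mirExon"], "exonic")
  expect_false("mirLonely" %in% h$mirna_id)
})

test_that("planted miRNA hosts are recovered exactly from generated fixtures", {
  fx <- random_fixture(704, n_sources = 2, pcg = 20, lnc = 15,
                       mir_in = 3, mir_ex = 2)$fx
  atlas <- merge_annotations(fx$sources)
  h <- mirna_hosts(atlas)
  planted <- fx$truth[fx$truth$role == "mirna", ]
  expect_equal(nrow(h), nrow(planted))
  m <- match(planted$gene_id, h$mirna_id)
  expect_false(anyNA(m))
  expect_equal(h$host_gene_id[m], planted$host_id)
  expect_equal(h$relation[m], planted$host_relation)
})
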