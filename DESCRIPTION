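Package: atlaskit
Title: Multi-Source Gene Atlas Construction and Tissue-Wise Functional
    Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an enriched gene annotation (atlas) by strand-aware,
    exon-level merging of multiple GTF gene catalogs in a stated priority
    order, scores transcription start sites against CAGE peaks, and
    functionally annotates the resulting genes from RNA-seq counts:
    TPM and TMM-scaled expression, per-tissue median profiles
    (median-of-project-medians), expressed-gene calling, tau
    tissue-specificity with gap-based specificity categories, positional
    classification of lncRNA and miRNA genes relative to their closest
    protein-coding gene, miRNA host-gene tabulation, and Kendall
    co-expression calling with Benjamini-Hochberg control. Includes a
    seeded synthetic-fixture generator (multi-source annotations with
    controlled overlap structure; negative-binomial counts with planted
    tissue-specific, sex-biased and co-regulated genes) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
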