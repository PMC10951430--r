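#' Gene biotype classes used throughout the package
#'
#' Raw biotype strings from the input GTFs are collapsed into five working
#' classes: protein-coding genes (`pcg`), long non-coding RNA genes
#' (`lncRNA`), `miRNA`, other small structural RNAs (`other_small_rna`) and
#' a catch-all `other`. Merging, overlap statistics, positional
#' classification and the census tables all operate on these classes.
#'
#' @export
BIOTYPE_CLASSES <- c("pcg", "lncRNA", "miRNA", "other_small_rna", "other")

#' Default raw-biotype to class mapping table
#'
#' Returns the mapping shipped with the package
#' (`inst/extdata/biotype_classes.tsv`), a two-column data.frame
#' (`raw_biotype`, `biotype_class`). The table is deliberately editable:
#' annotation sources differ in their biotype dialects, so
#' [normalize_biotype()] accepts any replacement table of the same shape.
#' Class labels map to themselves so normalization is idempotent.
#'
#' @param file Path to a TSV with columns `raw_biotype` and `biotype_class`;
#'   defaults to the table shipped with the package.
#' @return data.frame with columns `raw_biotype`, `biotype_class`.
#' @export
biotype_class_map <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "biotype_classes.tsv", package = "atlaskit")
  }
  if (!nzchar(file) || !file.exists(file)) .stopf("biotype map file not found: %s", file)
  map <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("raw_biotype", "biotype_class") %in% names(map))) {
    .stopf("biotype map must have columns raw_biotype and biotype_class")
  }
  bad <- setdiff(unique(map$biotype_class), BIOTYPE_CLASSES)
  if (length(bad)) .stopf("unknown biotype class in map: %s", paste(bad, collapse = ", "))
  map
}

#' Collapse raw biotype strings into working biotype classes
#'
#' Deterministic, total lookup: strings absent from the mapping table
#' (including `NA`) fall through to `"other"`. The mapping is idempotent on
#' its own output labels.
#'
#' @param raw_biotype Character vector of raw biotype strings.
#' @param map Mapping table, see [biotype_class_map()].
#' @return Character vector of classes (see [BIOTYPE_CLASSES]).
#' @examples
#' normalize_biotype(c("protein_coding", "lncRNA", "pseudogene", NA))
#' @export
normalize_biotype <- function(raw_biotype, map = biotype_class_map()) {
  idx <- match(raw_biotype, map$raw_biotype)
  out <- map$biotype_class[idx]
  out[is.na(out)] <- "other"
  out
}
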