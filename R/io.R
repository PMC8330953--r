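#' Read or write an OTU count table
#'
#' Count tables are tab-separated matrices: the first column holds OTU ids,
#' the header row holds sample ids, and cells hold non-negative integer
#' counts. This is the canonical on-disk dialect produced by
#' [generate_cohort()] and consumed by the QC and ecology stages.
#'
#' @param path Path to a TSV file.
#' @return A wide tibble with an `otu_id` column followed by one integer
#'   column per sample.
#' @export
read_otu_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "otu_id"
  x
}

#' @rdname read_otu_counts
#' @param counts A wide counts tibble (first column OTU ids).
#' @export
write_otu_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read or write a taxonomy map
#'
#' Two-column TSV: `otu_id` and a semicolon-delimited ranked lineage string
#' of the form `k__...;p__...;c__...;o__...;f__...;g__...;s__...`. Ranks may
#' be empty (unclassified below some level).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `otu_id` and `lineage`.
#' @export
read_taxonomy <- function(path) {
  readr::read_tsv(path, col_names = c("otu_id", "lineage"), skip = 1,
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_taxonomy
#' @param taxonomy Tibble with columns `otu_id`, `lineage`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy[, c("otu_id", "lineage")], path, progress = FALSE)
  invisible(path)
}

#' Read or write sample metadata
#'
#' One row per sample: `sample_id`, `farm`, `month` (integer index),
#' `texture` (one of `no_foam`, `crust`, `foam`) plus diet and manure
#' chemistry variables.
#'
#' @param path Path to a TSV file.
#' @return A tibble, `texture` as a factor with levels no_foam < crust < foam.
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("texture" %in% names(x)) {
    x$texture <- factor(x$texture, levels = texture_levels())
  }
  x
}

#' @rdname read_sample_metadata
#' @param metadata A metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

taxonomy_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

rank_prefixes <- function() {
  c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
    family = "f__", genus = "g__", species = "s__")
}

#' Split ranked lineage strings into one column per rank
#'
#' @param taxonomy Tibble with columns `otu_id` and `lineage`.
#' @return Tibble with `otu_id` plus the seven canonical rank columns;
#'   missing or explicitly "unclassified" fields become `NA`.
#' @export
parse_lineage <- function(taxonomy) {
  parts <- strsplit(taxonomy$lineage %||% "", ";", fixed = TRUE)
  ranks <- taxonomy_ranks()
  m <- matrix(NA_character_, nrow = length(parts), ncol = length(ranks),
              dimnames = list(NULL, ranks))
  pre <- rank_prefixes()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    for (j in seq_along(ranks)) {
      if (j > length(p)) break
      v <- sub(paste0("^", pre[j]), "", trimws(p[j]))
      if (nzchar(v) && tolower(v) != "unclassified") m[i, j] <- v
    }
  }
  dplyr::bind_cols(tibble::tibble(otu_id = taxonomy$otu_id),
                   tibble::as_tibble(m))
}
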