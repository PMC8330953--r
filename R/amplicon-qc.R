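#' Good's coverage of a sample
#'
#' Estimates sampling completeness as `1 - F1 / N`, where `F1` is the number
#' of OTUs observed exactly once in the sample and `N` its total reads.
#' Samples with low coverage were under-sequenced and are removed by
#' [filter_samples()].
#'
#' @param counts Non-negative integer vector of per-OTU counts for one
#'   sample.
#' @return Coverage in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) abort("all-zero count vector: coverage undefined")
  1 - sum(counts == 1) / n
}

qc_report <- function(sample_stats, removed, params) {
  structure(list(sample_stats = sample_stats, removed = removed,
                 params = params),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", nrow(x$removed), "removals\n")
  if (nrow(x$removed)) print(dplyr::count(x$removed, .data$kind, .data$reason))
  invisible(x)
}

#' Remove rare OTUs
#'
#' Drops OTUs observed fewer than `min_total` times across all samples
#' (default 5, the questionable-OTU rule used for both the 16S and mcrA
#' tables). The sample set is unchanged.
#'
#' @param counts Wide counts tibble (first column OTU ids).
#' @param min_total Minimum total count across samples for an OTU to be
#'   retained; must be >= 1.
#' @return A list with `counts` (filtered tibble) and `report`
#'   (a `qc_report`).
#' @export
filter_rare_otus <- function(counts, min_total = 5) {
  if (min_total < 1) abort("min_total must be >= 1")
  m <- check_counts(counts_to_matrix(counts))
  tot <- rowSums(m)
  keep <- tot >= min_total
  removed <- tibble::tibble(
    id = rownames(m)[!keep], kind = "otu",
    reason = sprintf("total count %d < %d", as.integer(tot[!keep]),
                     as.integer(min_total)),
    value = tot[!keep]
  )
  rep <- qc_report(
    sample_stats = tibble::tibble(sample_id = colnames(m), depth = colSums(m)),
    removed = removed,
    params = list(min_total = min_total)
  )
  list(counts = counts[keep, , drop = FALSE], report = rep)
}

#' Remove under-sequenced samples
#'
#' Drops samples with read depth below `min_reads` or Good's coverage below
#' `min_coverage`. The conventional presets are 10,000 reads / 0.97 coverage
#' for bacterial 16S tables and 4,000 reads / 0.99 coverage for methanogen
#' mcrA tables.
#'
#' @param counts Wide counts tibble.
#' @param min_reads Minimum per-sample read depth.
#' @param min_coverage Minimum Good's coverage.
#' @return A list with `counts` and `report`; the report lists each removed
#'   sample with the criterion it failed.
#' @export
filter_samples <- function(counts, min_reads = 10000, min_coverage = 0.97) {
  if (min_reads < 0 || min_coverage < 0) abort("thresholds must be >= 0")
  m <- check_counts(counts_to_matrix(counts))
  depth <- colSums(m)
  if (any(depth == 0)) abort("sample with zero reads")
  cov <- 1 - colSums(m == 1) / depth
  keep <- depth >= min_reads & cov >= min_coverage
  reason <- dplyr::case_when(
    depth < min_reads & cov < min_coverage ~
      sprintf("depth %d < %d and coverage %.4f < %.4f",
              as.integer(depth), as.integer(min_reads), cov, min_coverage),
    depth < min_reads ~ sprintf("depth %d < %d", as.integer(depth),
                                as.integer(min_reads)),
    cov < min_coverage ~ sprintf("coverage %.4f < %.4f", cov, min_coverage),
    TRUE ~ NA_character_
  )
  removed <- tibble::tibble(id = colnames(m)[!keep], kind = "sample",
                            reason = reason[!keep], value = depth[!keep])
  rep <- qc_report(
    sample_stats = tibble::tibble(sample_id = colnames(m), depth = depth,
                                  goods_coverage = cov, retained = keep),
    removed = removed,
    params = list(min_reads = min_reads, min_coverage = min_coverage)
  )
  id_col <- names(counts)[1]
  list(counts = counts[, c(id_col, colnames(m)[keep]), drop = FALSE],
       report = rep)
}

#' Full QC chain for one marker table
#'
#' Applies [filter_rare_otus()] then [filter_samples()], in that order.
#' Coverage is computed after the rare-OTU filter by default
#' (`coverage_on = "filtered"`); set `coverage_on = "raw"` to threshold on
#' coverage of the unfiltered table instead.
#'
#' @inheritParams filter_samples
#' @param min_total Rare-OTU threshold, see [filter_rare_otus()].
#' @param coverage_on Whether Good's coverage is evaluated on the
#'   OTU-filtered (`"filtered"`, default) or raw (`"raw"`) table.
#' @return A list with `counts` and `report` (removed OTUs and samples
#'   combined; parameters recorded).
#' @export
qc_pipeline <- function(counts, min_total = 5, min_reads = 10000,
                        min_coverage = 0.97,
                        coverage_on = c("filtered", "raw")) {
  coverage_on <- match.arg(coverage_on)
  s1 <- filter_rare_otus(counts, min_total)
  if (coverage_on == "filtered") {
    s2 <- filter_samples(s1$counts, min_reads, min_coverage)
    out <- s2$counts
    stats <- s2$report$sample_stats
    removed <- dplyr::bind_rows(s1$report$removed, s2$report$removed)
  } else {
    s2 <- filter_samples(counts, min_reads, min_coverage)
    keep <- s2$report$sample_stats$sample_id[s2$report$sample_stats$retained]
    out <- s1$counts[, c(names(counts)[1], keep), drop = FALSE]
    stats <- s2$report$sample_stats
    removed <- dplyr::bind_rows(s1$report$removed, s2$report$removed)
  }
  list(counts = out,
       report = qc_report(stats, removed,
                          list(min_total = min_total, min_reads = min_reads,
                               min_coverage = min_coverage,
                               coverage_on = coverage_on)))
}

#' Per-sample relative abundances
#'
#' Standardizes counts by the total number of sequences per sample; no
#' rarefaction is performed. Each sample column of the result sums to 1.
#'
#' @param counts Wide counts tibble; every sample must have depth > 0.
#' @return A wide tibble of the same shape with proportions.
#' @export
relative_abundance <- function(counts) {
  m <- counts_to_matrix(counts)
  depth <- colSums(m)
  if (any(depth == 0)) abort("zero-depth sample: relative abundance undefined")
  matrix_to_counts(sweep(m, 2, depth, "/"), id_col = names(counts)[1])
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums counts over OTUs sharing the same name at `rank`. OTUs unclassified
#' at that rank are pooled into an `unclassified <parent>` group, where the
#' parent is the deepest classified name above the rank (e.g. "unclassified
#' Archaea"). Per-sample totals are conserved exactly.
#'
#' @param counts Wide counts tibble.
#' @param taxonomy Tibble with `otu_id`, `lineage` covering the table's
#'   OTUs.
#' @param rank One of kingdom, phylum, class, order, family, genus, species.
#' @return A wide tibble whose first column `taxon` names the groups.
#' @export
aggregate_taxonomy <- function(counts, taxonomy, rank = "genus") {
  ranks <- taxonomy_ranks()
  if (!rank %in% ranks) abort(sprintf("unknown rank '%s'", rank))
  parsed <- parse_lineage(taxonomy)
  id_col <- names(counts)[1]
  idx <- match(counts[[id_col]], parsed$otu_id)
  if (anyNA(idx)) abort("taxonomy does not cover all OTUs in the table")
  parsed <- parsed[idx, ]
  j <- match(rank, ranks)
  label <- parsed[[rank]]
  unc <- is.na(label)
  if (any(unc)) {
    parent <- rep("unknown", sum(unc))
    above <- parsed[unc, ranks[seq_len(j - 1)], drop = FALSE]
    if (j > 1) {
      for (k in rev(seq_len(j - 1))) {
        fill <- parent == "unknown" & !is.na(above[[k]])
        parent[fill] <- above[[k]][fill]
      }
    }
    label[unc] <- paste("unclassified", parent)
  }
  m <- counts_to_matrix(counts)
  agg <- rowsum(m, group = label, reorder = TRUE)
  tibble::as_tibble(agg, rownames = "taxon")
}
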