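#' Core taxa of a texture group
#'
#' Selects taxa present (count > 0) in at least a `prevalence` fraction of
#' the group's samples; the default 1.0 keeps only taxa present in every
#' sample of the group, minimizing farm-specific signal. Run on the
#' QC-filtered table. As a convenience, `prevalence = 0` returns all taxa
#' with at least one occurrence in the group.
#'
#' @param counts Wide counts (or relative-abundance) tibble.
#' @param metadata Sample metadata with `sample_id` and the grouping
#'   column.
#' @param group Texture group.
#' @param prevalence Fraction in `(0, 1]` (or 0, see above).
#' @param group_col Grouping column name.
#' @return A tibble of class `core_set` with columns `group`, `otu_id`,
#'   `prevalence_observed`; the threshold is kept as an attribute.
#' @export
core_taxa <- function(counts, metadata, group, prevalence = 1.0,
                      group_col = "texture") {
  if (prevalence < 0 || prevalence > 1) {
    abort("prevalence must lie in [0, 1]")
  }
  ids <- metadata$sample_id[as.character(metadata[[group_col]]) == group &
                              !is.na(metadata[[group_col]])]
  ids <- intersect(names(counts)[-1], ids)
  if (!length(ids)) abort(sprintf("group '%s' has no samples", group))
  m <- counts_to_matrix(counts[, c(names(counts)[1], ids)])
  frac <- rowMeans(m > 0)
  keep <- frac > 0 & frac >= prevalence
  out <- tibble::tibble(group = group, otu_id = rownames(m)[keep],
                        prevalence_observed = frac[keep])
  class(out) <- c("core_set", class(out))
  attr(out, "prevalence_threshold") <- prevalence
  attr(out, "n_samples") <- length(ids)
  out
}

#' Shared and unique membership of core sets
#'
#' Partitions the union of two or three core sets into its disjoint Venn
#' regions and counts the members of each; counts sum to the union size.
#'
#' @param cores Named list of `core_set` tibbles or plain character
#'   vectors of taxon ids (2 or 3 sets).
#' @return A tibble with `region` (e.g. `"foam_only"`,
#'   `"no_foam&crust"`, `"no_foam&crust&foam"`) and `count`.
#' @export
venn_partition <- function(cores) {
  sets <- lapply(cores, function(s) {
    if (is.data.frame(s)) unique(s$otu_id) else unique(as.character(s))
  })
  k <- length(sets)
  if (k < 2 || k > 3) abort("venn_partition needs 2 or 3 sets")
  nm <- names(sets) %||% paste0("set", seq_len(k))
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pats <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1, drop = FALSE]
  pats <- pats[rowSums(pats) > 0, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(pats)), function(i) {
    want <- unlist(pats[i, ])
    cnt <- sum(apply(member, 1, function(r) all(r == want)))
    label <- if (sum(want) == 1) paste0(nm[want], "_only") else
      paste(nm[want], collapse = "&")
    tibble::tibble(region = label, count = as.integer(cnt))
  })
  dplyr::bind_rows(rows)
}

#' Bootstrap percentile confidence interval for a mean
#'
#' Percentile interval of the resampled mean (seeded, deterministic).
#'
#' @param x Numeric vector, n >= 5.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return A tibble with `lower`, `mean`, `upper`.
#' @export
bootstrap_ci <- function(x, n_boot = 999, level = 0.95, seed = NULL) {
  n <- length(x)
  if (n < 5) abort("need at least 5 observations")
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(x[sample.int(n, n, replace = TRUE)]), 0)
  qs <- quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(lower = qs[1], mean = mean(x), upper = qs[2])
}

#' Bayes-factor differential abundance across textures
#'
#' For each taxon of a rank-aggregated relative-abundance table, computes
#' the JZS one-way Bayes factor ([bf_anova()]) across the three texture
#' groups, per-texture mean relative abundances with bootstrap percentile
#' confidence intervals, and the texture in which the taxon is most
#' abundant. Conventional thresholds are `bf_threshold = 100` at genus
#' rank and `20` at species rank.
#'
#' @param relabund_at_rank Wide relative-abundance tibble, typically from
#'   [aggregate_taxonomy()] then [relative_abundance()]; first column
#'   taxon ids.
#' @param metadata Sample metadata with `sample_id` and the grouping
#'   column.
#' @param bf_threshold Bayes-factor significance threshold.
#' @param group_col Grouping column name.
#' @param n_boot,level Bootstrap CI settings.
#' @param seed Optional integer seed.
#' @return A tibble of class `diff_abundance`: per taxon, `bf10`,
#'   `significant`, `most_abundant_in`, and per-texture `mean_*`, `lo_*`,
#'   `hi_*` columns.
#' @export
differential_abundance <- function(relabund_at_rank, metadata,
                                   bf_threshold = 100,
                                   group_col = "texture", n_boot = 999,
                                   level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id_col <- names(relabund_at_rank)[1]
  m <- counts_to_matrix(relabund_at_rank, id_col = id_col)
  idx <- match(colnames(m), metadata$sample_id)
  if (anyNA(idx)) abort("metadata does not cover all samples")
  g <- droplevels(factor(metadata[[group_col]][idx]))
  if (nlevels(g) < 2) abort("need at least 2 texture groups")
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    bf <- tryCatch(bf_anova(y, g), error = function(e) NA_real_)
    by_g <- split(y, g)
    stats <- lapply(by_g, function(v) {
      if (length(v) >= 5) bootstrap_ci(v, n_boot = n_boot, level = level)
      else tibble::tibble(lower = NA_real_, mean = mean(v), upper = NA_real_)
    })
    means <- vapply(stats, `[[`, 0, "mean")
    row <- tibble::tibble(taxon = rownames(m)[i], bf10 = bf,
                          most_abundant_in = names(which.max(means)))
    for (lv in names(stats)) {
      row[[paste0("mean_", lv)]] <- stats[[lv]]$mean
      row[[paste0("lo_", lv)]] <- stats[[lv]]$lower
      row[[paste0("hi_", lv)]] <- stats[[lv]]$upper
    }
    row
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$bf10))
  out$significant <- !is.na(out$bf10) & out$bf10 >= bf_threshold
  class(out) <- c("diff_abundance", class(out))
  attr(out, "bf_threshold") <- bf_threshold
  out
}
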