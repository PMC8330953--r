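#' Texture proportions over time with linear trends
#'
#' Computes, for each month, the proportion of samples showing each surface
#' texture (proportions sum to 1 within month), and fits an ordinary
#' least-squares line of proportion versus month index per texture.
#'
#' @param metadata Sample metadata with `month` and the texture column;
#'   needs >= 2 months. Months with zero samples are simply absent.
#' @param texture_col Grouping column name.
#' @return An object of class `texture_trends` with `proportions` (tibble:
#'   `month`, `texture`, `n`, `proportion`) and `slopes` (tibble:
#'   `texture`, `slope`, `intercept`).
#' @export
texture_trends <- function(metadata, texture_col = "texture") {
  md <- metadata[!is.na(metadata[[texture_col]]), ]
  if (length(unique(md$month)) < 2) abort("need at least 2 months")
  props <- md %>%
    dplyr::count(.data$month, texture = factor(.data[[texture_col]])) %>%
    tidyr::complete(.data$month, .data$texture, fill = list(n = 0L)) %>%
    dplyr::group_by(.data$month) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  slopes <- props %>%
    dplyr::group_by(.data$texture) %>%
    dplyr::summarise(
      slope = coef(lm(proportion ~ month))[[2]],
      intercept = coef(lm(proportion ~ month))[[1]],
      .groups = "drop")
  structure(list(proportions = props, slopes = slopes),
            class = "texture_trends")
}

#' @export
print.texture_trends <- function(x, ...) {
  cat("Texture proportions over",
      length(unique(x$proportions$month)), "months\n")
  print(x$slopes)
  invisible(x)
}

#' Pipeline run configuration
#'
#' Describes one end-to-end analysis run: either paths to on-disk tables
#' (`input`) or a synthetic [cohort_config()] (`synthetic`) — exactly one
#' of the two — plus per-stage parameters, an output directory, and the
#' global seed used for every stochastic stage.
#'
#' @param input Named list of paths: `counts_16s`, `taxonomy_16s`,
#'   `counts_mcra`, `taxonomy_mcra`, `metadata` (all TSV dialects of this
#'   package). `NULL` when running synthetically.
#' @param synthetic A [cohort_config()], or `NULL`.
#' @param outdir Output directory.
#' @param seed Integer seed for all stochastic stages.
#' @param stages Which stages to run, a subset of the default vector.
#' @param params Named list overriding stage parameters:
#'   `qc_16s`/`qc_mcra` (min_total, min_reads, min_coverage), `permanova`
#'   (n_perm), `nmds` (k, n_restarts, max_iter), `trends` (variables,
#'   bf_threshold, n_draws), `correlations` (pairs, alpha, top_k, n_perm),
#'   `stability` (n_boot), `cores` (rank, prevalence, bf_threshold).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, outdir,
                            seed = 1L,
                            stages = c("qc", "ecology", "trends",
                                       "correlations", "stability", "cores",
                                       "texture_trends"),
                            params = list()) {
  if (is.null(input) == is.null(synthetic)) {
    abort("exactly one of `input` or `synthetic` must be given")
  }
  if (!is.null(input)) {
    need <- c("counts_16s", "taxonomy_16s", "counts_mcra", "taxonomy_mcra",
              "metadata")
    if (!all(need %in% names(input))) {
      abort(paste("input must name:", paste(need, collapse = ", ")))
    }
  }
  defaults <- list(
    qc_16s = list(min_total = 5, min_reads = 10000, min_coverage = 0.97),
    qc_mcra = list(min_total = 5, min_reads = 4000, min_coverage = 0.99),
    permanova = list(n_perm = 999),
    nmds = list(k = 2, n_restarts = 4, max_iter = 100),
    trends = list(variables = c("SBM", "DDGS", "crude_protein", "NDF",
                                "ADF", "crude_fiber", "MPR", "organic_N",
                                "temperature", "manure_depth"),
                  bf_threshold = 3, n_draws = 10000),
    correlations = list(
      pairs = tibble::tibble(
        var_a = c("LCFA", "LCFA", "SCFA", "SCFA", "acetic_acid", "MPR"),
        var_b = c("SCFA", "acetic_acid", "acetic_acid", "pH", "pH",
                  "organic_N")),
      alpha = 0.05, top_k = 5, n_perm = 199),
    stability = list(n_boot = 999),
    cores = list(rank = "genus", prevalence = 1.0, bf_threshold = 100)
  )
  for (nm in names(params)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]] %||% list(),
                                        params[[nm]])
  }
  structure(list(input = input, synthetic = synthetic, outdir = outdir,
                 seed = as.integer(seed), stages = stages,
                 params = defaults),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    list(counts_16s = cohort$counts_16s, taxonomy_16s = cohort$taxonomy_16s,
         counts_mcra = cohort$counts_mcra,
         taxonomy_mcra = cohort$taxonomy_mcra,
         metadata = cohort$metadata, cohort = cohort)
  } else {
    list(counts_16s = read_otu_counts(config$input$counts_16s),
         taxonomy_16s = read_taxonomy(config$input$taxonomy_16s),
         counts_mcra = read_otu_counts(config$input$counts_mcra),
         taxonomy_mcra = read_taxonomy(config$input$taxonomy_mcra),
         metadata = read_sample_metadata(config$input$metadata),
         cohort = NULL)
  }
}

#' Run the full deep-pit foaming analysis pipeline
#'
#' Executes the configured stages in order for both markers (16S with the
#' 10,000-read / 0.97-coverage preset, mcrA with 4,000 / 0.99): QC,
#' Bray-Curtis + farm- and texture-PERMANOVA (farm-stratified) + NMDS +
#' MPR surface, diet/manure Bayes trend table, correlation screen,
#' stability bootstrap with overlap coefficients, core communities with
#' Venn partition and genus-level differential abundance, and texture
#' proportion trends. Every result is written as TSV under `outdir`
#' together with a JSON manifest recording stage parameters, the seed and
#' md5 hashes of all outputs; identical config and seed reproduce
#' identical hashes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results (`qc`, `ecology`,
#'   `trends`, `correlations`, `stability`, `cores`, `texture_trends`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  inputs <- load_pipeline_inputs(config)
  meta <- inputs$metadata
  p <- config$params
  res <- list()
  files <- character()
  wr <- function(x, name) {
    path <- file.path(config$outdir, name)
    readr::write_tsv(x, path, progress = FALSE)
    files <<- c(files, path)
    path
  }
  markers <- list(
    `16s` = list(counts = inputs$counts_16s, tax = inputs$taxonomy_16s,
                 qc = p$qc_16s),
    mcra = list(counts = inputs$counts_mcra, tax = inputs$taxonomy_mcra,
                qc = p$qc_mcra))

  # --- qc (always needed downstream)
  qc <- lapply(markers, function(mk) {
    do.call(qc_pipeline, c(list(mk$counts), mk$qc))
  })
  res$qc <- qc
  for (mk in names(qc)) {
    wr(qc[[mk]]$report$sample_stats, sprintf("qc_sample_stats_%s.tsv", mk))
    wr(qc[[mk]]$report$removed, sprintf("qc_removed_%s.tsv", mk))
  }
  relab <- lapply(qc, function(q) relative_abundance(q$counts))
  meta_by <- lapply(relab, function(r) {
    meta[meta$sample_id %in% names(r)[-1], ]
  })

  if ("ecology" %in% config$stages) {
    res$ecology <- lapply(names(markers), function(mk) {
      r <- relab[[mk]]; md <- meta_by[[mk]]
      d <- bray_curtis(r)
      pv_farm <- permanova(md, d, farm, n_perm = p$permanova$n_perm)
      pv_tex <- permanova(md, d, texture, strata = farm,
                          n_perm = p$permanova$n_perm)
      ord <- nmds(d, k = p$nmds$k, n_restarts = p$nmds$n_restarts,
                  max_iter = p$nmds$max_iter)
      mpr <- if ("MPR" %in% names(md)) {
        fit_env_surface(ord, md$MPR[match(ord$coordinates$sample_id,
                                          md$sample_id)])
      } else NULL
      tab <- dplyr::bind_rows(glance(pv_farm), glance(pv_tex))
      wr(tab, sprintf("permanova_%s.tsv", mk))
      wr(ord$coordinates, sprintf("nmds_coordinates_%s.tsv", mk))
      list(marker = mk, dist = d, permanova_farm = pv_farm,
           permanova_texture = pv_tex, nmds = ord, mpr_surface = mpr)
    })
    names(res$ecology) <- names(markers)
  }

  if ("trends" %in% config$stages) {
    vars <- intersect(p$trends$variables, names(meta))
    res$trends <- trend_table(meta, vars, bf_threshold = p$trends$bf_threshold,
                              n_draws = p$trends$n_draws)
    wr(dplyr::select(res$trends, -"ordering"), "trend_table.tsv")
  }

  if ("correlations" %in% config$stages) {
    pr <- p$correlations$pairs
    pr <- pr[pr$var_a %in% names(meta) & pr$var_b %in% names(meta), ]
    res$correlations <- screen_correlations(
      meta, pr, alpha = p$correlations$alpha, top_k = p$correlations$top_k,
      n_perm = p$correlations$n_perm)
    wr(res$correlations, "correlation_screen.tsv")
    wr(screen_edges(res$correlations), "correlation_edges.tsv")
  }

  if ("stability" %in% config$stages) {
    res$stability <- stability_comparison(
      relab[["16s"]], meta_by[["16s"]], n_boot = p$stability$n_boot)
    wr(tidy(res$stability), "stability_slopes.tsv")
    ovl <- res$stability$overlap
    ovl_all <- dplyr::bind_rows(
      ovl, tibble::tibble(group_a = "no_foam", group_b = "crust+foam",
                          ovl = res$stability$pooled_overlap))
    wr(ovl_all, "stability_overlap.tsv")
  }

  if ("cores" %in% config$stages) {
    res$cores <- lapply(names(markers), function(mk) {
      q <- qc[[mk]]; md <- meta_by[[mk]]
      present <- intersect(texture_levels(),
                           unique(as.character(md$texture)))
      cores <- lapply(present, function(gv) {
        core_taxa(q$counts, md, gv, prevalence = p$cores$prevalence)
      })
      names(cores) <- present
      venn <- if (length(cores) >= 2) venn_partition(cores) else NULL
      agg <- aggregate_taxonomy(q$counts, markers[[mk]]$tax,
                                rank = p$cores$rank)
      da <- differential_abundance(relative_abundance(agg), md,
                                   bf_threshold = p$cores$bf_threshold)
      if (!is.null(venn)) wr(venn, sprintf("core_venn_%s.tsv", mk))
      wr(da, sprintf("differential_abundance_%s.tsv", mk))
      list(cores = cores, venn = venn, diff_abundance = da)
    })
    names(res$cores) <- names(markers)
  }

  if ("texture_trends" %in% config$stages) {
    res$texture_trends <- texture_trends(meta)
    wr(res$texture_trends$proportions, "texture_proportions.tsv")
    wr(res$texture_trends$slopes, "texture_trend_slopes.tsv")
  }

  manifest <- list(
    package = "pitfoam",
    version = as.character(packageVersion("pitfoam")),
    seed = config$seed,
    stages = config$stages,
    params = lapply(p, function(z) {
      lapply(z, function(v) if (is.data.frame(v)) as.list(v) else v)
    }),
    input_mode = if (is.null(config$synthetic)) "files" else "synthetic",
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files)))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
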