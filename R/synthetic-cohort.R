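#' Configuration for a synthetic deep-pit manure cohort
#'
#' Describes the generative model for a multi-farm, multi-month amplicon
#' survey of storage-pit manure: one sample per (farm, month), a first-order
#' Markov chain over surface textures (`no_foam`, `crust`, `foam`) per farm,
#' logistic-normal community composition with additive farm, texture and
#' random-walk drift effects on the log scale, multinomial read sampling at
#' negative-binomial depths, and Gaussian diet/chemistry variables with
#' ordered texture means and planted within-texture correlations.
#'
#' Defaults mirror the field study the package is designed around: 46 farms
#' sampled over 13 months, persistent textures, strong farm-level community
#' blocking (farm effect sd well above the texture effect sd), non-foaming
#' communities drifting fastest, diet variables ordered across textures
#' (e.g. DDGS and methane production rate highest under foam, soybean meal
#' highest under no-foam), and a long-chain/short-chain fatty acid
#' correlation planted in foam samples only.
#'
#' @param n_farms,n_months Cohort dimensions; one sample per farm-month
#'   before missingness.
#' @param n_bacterial_otus,n_methanogen_otus Core OTU richness for the 16S
#'   and mcrA tables (rare singleton OTUs come on top, see
#'   `singleton_rate_*`).
#' @param mean_depth_16s,mean_depth_mcra Mean sequencing depth (reads); per
#'   sample depths are negative binomial with dispersion `depth_dispersion`
#'   so a realistic fraction of samples falls below the QC thresholds.
#' @param depth_dispersion Negative-binomial size parameter for depths.
#' @param farm_effect_sd,texture_effect_sd Standard deviations of the
#'   per-OTU Gaussian farm and texture effects on the log-abundance scale;
#'   either a single value for both markers or a vector named `16s` and
#'   `mcra`. The defaults make the farm block dominate community variance
#'   for both markers (much more strongly for methanogens), with a
#'   detectable but smaller texture signal, matching the variance
#'   hierarchy such surveys report.
#' @param drift_rate Named numeric, per-month random-walk step sd on the log
#'   scale for each texture; larger means the community decays faster over
#'   time (the default orders no_foam > crust > foam).
#' @param texture_transition 3x3 row-stochastic matrix over
#'   (no_foam, crust, foam), rows = from, columns = to.
#' @param texture_init Initial texture distribution at month 1.
#' @param diet_means Tibble with columns `variable`, `no_foam`, `crust`,
#'   `foam`, `sd`: per-texture Gaussian means and a common sd for each diet
#'   or manure-chemistry variable. See [default_diet_means()].
#' @param planted_correlations List of lists with fields `var_a`, `var_b`,
#'   `texture`, `rho`, `shape` ("monotonic" or "quadratic"); each induces
#'   the stated dependence between the two variables within that texture
#'   only.
#' @param planted_enrichment List of lists with fields `marker` ("16s" or
#'   "mcra"), `otu` (index), `texture`, `effect` (log-scale boost); planted
#'   differentially abundant taxa with known ground truth.
#' @param singleton_rate_16s,singleton_rate_mcra Expected fraction of a
#'   sample's reads that land on sample-level singleton OTUs (drawn from a
#'   shared rare-OTU pool), making Good's coverage nontrivially below 1.
#'   Per-sample rates are Gamma-distributed around these means.
#' @param rare_pool_16s,rare_pool_mcra Size of the shared rare-OTU pools.
#' @param base_logabund_sd Spread of baseline OTU log-abundances (community
#'   evenness).
#' @param missing_rate Fraction of farm-months dropped at random (sampling
#'   attrition; per-farm sample counts after attrition are not a published
#'   quantity, so it is exposed as a parameter rather than guessed).
#' @param seed Integer; the single global seed from which the whole cohort
#'   is drawn. Identical config + seed gives bit-identical output.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_farms = 46,
                          n_months = 13,
                          n_bacterial_otus = 300,
                          n_methanogen_otus = 60,
                          mean_depth_16s = 20000,
                          mean_depth_mcra = 8000,
                          depth_dispersion = 5,
                          farm_effect_sd = c(`16s` = 0.14, mcra = 0.50),
                          texture_effect_sd = c(`16s` = 0.12, mcra = 0.40),
                          drift_rate = c(no_foam = 0.10, crust = 0.04, foam = 0.02),
                          texture_transition = default_texture_transition(),
                          texture_init = c(no_foam = 0.5, crust = 0.1, foam = 0.4),
                          diet_means = default_diet_means(),
                          planted_correlations = default_planted_correlations(),
                          planted_enrichment = default_planted_enrichment(),
                          singleton_rate_16s = 0.015,
                          singleton_rate_mcra = 0.004,
                          rare_pool_16s = 2000,
                          rare_pool_mcra = 400,
                          base_logabund_sd = 1.5,
                          missing_rate = 0.05,
                          seed = 1L) {
  cfg <- list(
    n_farms = as.integer(n_farms), n_months = as.integer(n_months),
    n_bacterial_otus = as.integer(n_bacterial_otus),
    n_methanogen_otus = as.integer(n_methanogen_otus),
    mean_depth_16s = mean_depth_16s, mean_depth_mcra = mean_depth_mcra,
    depth_dispersion = depth_dispersion,
    farm_effect_sd = farm_effect_sd, texture_effect_sd = texture_effect_sd,
    drift_rate = drift_rate,
    texture_transition = texture_transition, texture_init = texture_init,
    diet_means = diet_means,
    planted_correlations = planted_correlations,
    planted_enrichment = planted_enrichment,
    singleton_rate_16s = singleton_rate_16s,
    singleton_rate_mcra = singleton_rate_mcra,
    rare_pool_16s = as.integer(rare_pool_16s),
    rare_pool_mcra = as.integer(rare_pool_mcra),
    base_logabund_sd = base_logabund_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  sizes <- c(cfg$n_farms, cfg$n_months, cfg$n_bacterial_otus,
             cfg$n_methanogen_otus, cfg$mean_depth_16s, cfg$mean_depth_mcra)
  if (any(sizes <= 0)) abort("all sizes and depths must be positive")
  if (any(cfg$farm_effect_sd < 0) || any(cfg$texture_effect_sd < 0) ||
      any(cfg$drift_rate < 0) || cfg$base_logabund_sd < 0) {
    abort("variance parameters must be non-negative")
  }
  tm <- cfg$texture_transition
  if (!is.matrix(tm) || any(dim(tm) != c(3, 3)) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-12)) {
    abort("texture_transition must be a 3x3 row-stochastic matrix")
  }
  if (abs(sum(cfg$texture_init) - 1) > 1e-12 || any(cfg$texture_init < 0)) {
    abort("texture_init must be a probability vector over the three textures")
  }
  if (!all(texture_levels() %in% names(cfg$drift_rate))) {
    abort("drift_rate must name all three textures")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  need <- c("variable", "no_foam", "crust", "foam", "sd")
  if (!all(need %in% names(cfg$diet_means))) {
    abort("diet_means must have columns variable, no_foam, crust, foam, sd")
  }
  invisible(cfg)
}

#' @rdname cohort_config
#' @export
default_texture_transition <- function() {
  m <- rbind(no_foam = c(0.88, 0.07, 0.05),
             crust   = c(0.04, 0.92, 0.04),
             foam    = c(0.03, 0.05, 0.92))
  colnames(m) <- texture_levels()
  m
}

#' Default per-texture means for diet and manure variables
#'
#' Group means are ordered the way the motivating field data are: soybean
#' meal highest under no-foam; DDGS, NDF and methane production rate (MPR)
#' highest under foam; crude protein, ADF, crude fiber, temperature and
#' manure depth highest under crust; organic N foam > no-foam > crust;
#' short-chain fatty acids and acetic acid accumulate in no-foam manure;
#' long-chain fatty acids accumulate in crust. Units follow field
#' conventions (percent of diet for feed ingredients and fiber fractions,
#' mg/g for fatty acids, L CH4 / L manure / day for MPR, degrees C, m).
#'
#' @return A tibble with columns `variable`, `no_foam`, `crust`, `foam`, `sd`.
#' @export
default_diet_means <- function() {
  tibble::tribble(
    ~variable,       ~no_foam, ~crust, ~foam,  ~sd,
    "SBM",               25.0,   20.0,  16.0,  4.0,
    "DDGS",              12.0,   19.0,  25.0,  5.0,
    "crude_protein",     13.5,   15.5,  14.5,  1.2,
    "NDF",                9.5,   11.5,  13.5,  1.5,
    "ADF",                3.2,    4.4,   3.8,  0.5,
    "crude_fiber",        2.4,    3.4,   2.9,  0.4,
    "MPR",               0.04,   0.08,  0.15, 0.03,
    "SCFA",              12.4,   10.0,   7.3,  2.5,
    "acetic_acid",        7.5,    6.0,   4.0,  1.5,
    "LCFA",               1.0,   15.0,   0.7,  0.5,
    "organic_N",         28.0,   24.0,  32.0,  4.0,
    "pH",                 8.2,    8.2,   8.2,  0.3,
    "temperature",       16.0,   22.0,  19.0,  2.5,
    "manure_depth",       1.4,    2.2,   1.8,  0.3
  )
}

#' @rdname cohort_config
#' @export
default_planted_correlations <- function() {
  list(list(var_a = "LCFA", var_b = "SCFA", texture = "foam",
            rho = 0.8, shape = "monotonic"))
}

#' @rdname cohort_config
#' @export
default_planted_enrichment <- function() {
  list(list(marker = "16s", otu = 1L, texture = "foam", effect = 2.0),
       list(marker = "mcra", otu = 1L, texture = "foam", effect = 2.0))
}

marker_param <- function(x, marker) {
  if (length(x) == 1) x[[1]] else x[[marker]]
}

softmax_cols <- function(m) {
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  sweep(e, 2, colSums(e), "/")
}

# synthetic ranked lineages; a slice of OTUs is left unclassified at genus
# (and deeper) so taxonomy pooling is exercised
synth_taxonomy <- function(n, marker) {
  if (marker == "16s") {
    phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Spirochaetes")
    classes <- list(Firmicutes = c("Clostridia", "Bacilli", "Erysipelotrichia"),
                    Bacteroidetes = "Bacteroidia",
                    Proteobacteria = c("Gammaproteobacteria", "Deltaproteobacteria"),
                    Spirochaetes = "Spirochaetia")
    kingdom <- "Bacteria"
    n_genera <- 40
  } else {
    phyla <- "Euryarchaeota"
    classes <- list(Euryarchaeota = c("Methanobacteria", "Methanomicrobia"))
    kingdom <- "Archaea"
    n_genera <- 12
  }
  g_phy <- sample(phyla, n_genera, replace = TRUE)
  g_cls <- vapply(g_phy, function(p) sample(rep(classes[[p]], 2), 1), "")
  g_name <- sprintf("Genus%s%02d", toupper(substr(marker, 1, 1)), seq_len(n_genera))
  gi <- sample.int(n_genera, n, replace = TRUE)
  unc_g <- runif(n) < 0.10   # unclassified at genus level
  unc_c <- runif(n) < 0.05   # unclassified below phylum
  lineage <- sprintf("k__%s;p__%s;c__%s;o__;f__;g__%s;s__%s",
                     kingdom, g_phy[gi],
                     ifelse(unc_c, "", g_cls[gi]),
                     ifelse(unc_g | unc_c, "", g_name[gi]),
                     ifelse(unc_g | unc_c, "",
                            paste0(tolower(g_name[gi]), "_sp", seq_len(n))))
  lineage
}

draw_marker_table <- function(cfg, marker, farms, months, textures_fm, keep) {
  n_otus <- if (marker == "16s") cfg$n_bacterial_otus else cfg$n_methanogen_otus
  mean_depth <- if (marker == "16s") cfg$mean_depth_16s else cfg$mean_depth_mcra
  singleton_rate <- if (marker == "16s") cfg$singleton_rate_16s else cfg$singleton_rate_mcra
  pool_n <- if (marker == "16s") cfg$rare_pool_16s else cfg$rare_pool_mcra
  tag <- if (marker == "16s") "OTU16S" else "OTUMCRA"

  fsd <- marker_param(cfg$farm_effect_sd, marker)
  tsd <- marker_param(cfg$texture_effect_sd, marker)
  nf <- cfg$n_farms; nm <- cfg$n_months
  base <- rnorm(n_otus, 0, cfg$base_logabund_sd)
  farm_eff <- matrix(rnorm(n_otus * nf, 0, fsd), n_otus, nf)
  tex_eff <- matrix(rnorm(n_otus * 3, 0, tsd), n_otus, 3,
                    dimnames = list(NULL, texture_levels()))
  for (pe in cfg$planted_enrichment) {
    if (identical(pe$marker, marker) && pe$otu <= n_otus) {
      tex_eff[pe$otu, pe$texture] <- tex_eff[pe$otu, pe$texture] + pe$effect
    }
  }
  # per-farm random-walk drift, step sd set by the month's texture
  drift <- array(0, dim = c(n_otus, nf, nm))
  for (f in seq_len(nf)) {
    acc <- numeric(n_otus)
    for (m in seq_len(nm)) {
      step_sd <- cfg$drift_rate[[textures_fm[f, m]]]
      acc <- acc + rnorm(n_otus, 0, step_sd)
      drift[, f, m] <- acc
    }
  }
  n_samp <- length(farms)
  latent <- matrix(0, n_otus, n_samp)
  for (i in seq_len(n_samp)) {
    f <- farms[i]; m <- months[i]
    latent[, i] <- base + farm_eff[, f] + tex_eff[, textures_fm[f, m]] +
      drift[, f, m]
  }
  latent <- softmax_cols(latent)

  depth <- pmax(rnbinom(n_samp, size = cfg$depth_dispersion, mu = mean_depth), 1L)
  sing_rate <- pmin(rgamma(n_samp, shape = 2, rate = 2 / singleton_rate), 0.2)
  n_sing <- rbinom(n_samp, depth, sing_rate)
  n_sing <- pmin(n_sing, pool_n)

  counts <- matrix(0L, n_otus, n_samp)
  for (i in seq_len(n_samp)) {
    counts[, i] <- rmultinom(1, depth[i] - n_sing[i], latent[, i])
  }
  rare <- matrix(0L, pool_n, n_samp)
  for (i in seq_len(n_samp)) {
    if (n_sing[i] > 0) rare[sample.int(pool_n, n_sing[i]), i] <- 1L
  }
  core_ids <- sprintf("%s_%04d", tag, seq_len(n_otus))
  rare_ids <- sprintf("%s_R%04d", tag, seq_len(pool_n))
  all_counts <- rbind(counts, rare)
  rownames(all_counts) <- c(core_ids, rare_ids)
  kingdom <- if (marker == "16s") "Bacteria" else "Archaea"
  lineage <- c(synth_taxonomy(n_otus, marker),
               rep(sprintf("k__%s;p__;c__;o__;f__;g__;s__", kingdom), pool_n))

  sample_ids <- sprintf("F%02d_M%02d", farms, months)
  colnames(all_counts) <- sample_ids
  all_counts <- all_counts[, keep, drop = FALSE]

  list(counts = matrix_to_counts(all_counts),
       taxonomy = tibble::tibble(otu_id = c(core_ids, rare_ids),
                                 lineage = lineage),
       latent = latent[, keep, drop = FALSE],
       tex_eff = tex_eff,
       depth = depth[keep])
}

#' Generate a synthetic deep-pit manure cohort
#'
#' Draws the full cohort described by a [cohort_config()]: a bacterial 16S
#' and a methanogen mcrA OTU count table (tab-matrix dialect), sample
#' metadata with diet and manure-chemistry variables, and a ground-truth
#' record of every planted signal so downstream stages can be validated
#' against known answers.
#'
#' @param config A [cohort_config()].
#' @return A list of class `manure_cohort` with elements `counts_16s`,
#'   `taxonomy_16s`, `counts_mcra`, `taxonomy_mcra`, `metadata` and `truth`
#'   (latent compositions, texture trajectories, texture effects, planted
#'   trends/correlations/enrichments, drift rates).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)
  nf <- cfg$n_farms; nm <- cfg$n_months
  lev <- texture_levels()

  # per-farm texture Markov chains
  textures_fm <- matrix("", nf, nm)
  for (f in seq_len(nf)) {
    s <- sample(lev, 1, prob = cfg$texture_init)
    textures_fm[f, 1] <- s
    for (m in seq_len(nm)[-1]) {
      s <- sample(lev, 1, prob = cfg$texture_transition[s, ])
      textures_fm[f, m] <- s
    }
  }

  farms <- rep(seq_len(nf), each = nm)
  months <- rep(seq_len(nm), times = nf)
  keep <- runif(length(farms)) >= cfg$missing_rate
  sample_ids <- sprintf("F%02d_M%02d", farms, months)

  t16 <- draw_marker_table(cfg, "16s", farms, months, textures_fm, keep)
  tmc <- draw_marker_table(cfg, "mcra", farms, months, textures_fm, keep)

  texture <- textures_fm[cbind(farms, months)]
  meta <- tibble::tibble(
    sample_id = sample_ids,
    farm = sprintf("F%02d", farms),
    month = months,
    texture = factor(texture, levels = lev)
  )[keep, ]

  # diet and chemistry: independent z-scores, then planted within-texture
  # dependence, then per-texture location/scale
  dm <- cfg$diet_means
  ns <- nrow(meta)
  z <- matrix(rnorm(ns * nrow(dm)), ns, nrow(dm),
              dimnames = list(NULL, dm$variable))
  for (pc in cfg$planted_correlations) {
    idx <- which(meta$texture == pc$texture)
    if (!length(idx)) next
    za <- z[idx, pc$var_a]
    zb <- z[idx, pc$var_b]
    z[idx, pc$var_b] <- switch(
      pc$shape,
      monotonic = pc$rho * za + sqrt(1 - pc$rho^2) * zb,
      quadratic = pc$rho * (za^2 - 1) / sqrt(2) + sqrt(1 - pc$rho^2) * zb,
      abort("planted correlation shape must be monotonic or quadratic")
    )
  }
  ti <- as.integer(meta$texture)
  for (j in seq_len(nrow(dm))) {
    mu <- c(dm$no_foam[j], dm$crust[j], dm$foam[j])[ti]
    meta[[dm$variable[j]]] <- mu + dm$sd[j] * z[, j]
  }

  truth <- list(
    textures = textures_fm,
    latent_16s = t16$latent, latent_mcra = tmc$latent,
    texture_effects_16s = t16$tex_eff, texture_effects_mcra = tmc$tex_eff,
    drift_rate = cfg$drift_rate,
    diet_means = dm,
    planted_correlations = cfg$planted_correlations,
    planted_enrichment = cfg$planted_enrichment
  )

  structure(list(counts_16s = t16$counts, taxonomy_16s = t16$taxonomy,
                 counts_mcra = tmc$counts, taxonomy_mcra = tmc$taxonomy,
                 metadata = meta, truth = truth, config = cfg),
            class = "manure_cohort")
}

#' @export
print.manure_cohort <- function(x, ...) {
  cat("<manure_cohort>", nrow(x$metadata), "samples,",
      x$config$n_farms, "farms x", x$config$n_months, "months\n")
  cat("  16S OTUs:", nrow(x$counts_16s),
      " mcrA OTUs:", nrow(x$counts_mcra), "\n")
  cat("  textures:", paste(names(table(x$metadata$texture)),
                           table(x$metadata$texture), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort's tables to a directory in the canonical TSV dialects
#'
#' @param cohort A `manure_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_counts(cohort$counts_16s, file.path(dir, "counts_16s.tsv"))
  write_otu_counts(cohort$counts_mcra, file.path(dir, "counts_mcra.tsv"))
  write_taxonomy(cohort$taxonomy_16s, file.path(dir, "taxonomy_16s.tsv"))
  write_taxonomy(cohort$taxonomy_mcra, file.path(dir, "taxonomy_mcra.tsv"))
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
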