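# small cohort used by several module tests
small_cohort_config <- function(seed = 1, ...) {
  defaults <- list(n_farms = 8, n_months = 6, n_bacterial_otus = 60,
                   n_methanogen_otus = 20, mean_depth_16s = 4000,
                   mean_depth_mcra = 2000, rare_pool_16s = 200,
                   rare_pool_mcra = 80, missing_rate = 0, seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# tiny deterministic counts table
toy_counts <- function() {
  tibble::tibble(
    otu_id = c("o1", "o2", "o3", "o4"),
    s1 = c(5L, 2L, 3L, 0L),
    s2 = c(3L, 1L, 2L, 0L),
    s3 = c(2L, 1L, 0L, 0L)
  )
}

toy_taxonomy <- function() {
  tibble::tibble(
    otu_id = c("o1", "o2", "o3", "o4"),
    lineage = c("k__Bacteria;p__Firmicutes;c__Clostridia;o__;f__;g__A;s__a1",
                "k__Bacteria;p__Firmicutes;c__Clostridia;o__;f__;g__A;s__a2",
                "k__Bacteria;p__Firmicutes;c__Bacilli;o__;f__;g__;s__",
                "k__Bacteria;p__;c__;o__;f__;g__;s__")
  )
}

# metadata + relabund pair for a hand-built two-farm series
toy_series <- function(comps, farms, months, textures) {
  ids <- sprintf("s%02d", seq_along(farms))
  colnames(comps) <- ids
  list(
    relabund = tibble::as_tibble(comps, rownames = "otu_id"),
    metadata = tibble::tibble(sample_id = ids, farm = farms,
                              month = months,
                              texture = factor(textures,
                                               levels = c("no_foam", "crust",
                                                          "foam")))
  )
}
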