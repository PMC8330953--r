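make_core_fixture <- function() {
  counts <- tibble::tibble(
    otu_id = paste0("o", 1:4),
    s1 = c(3L, 1L, 0L, 1L),
    s2 = c(2L, 1L, 1L, 0L),
    s3 = c(5L, 0L, 2L, 0L),
    s4 = c(1L, 4L, 3L, 0L),
    s5 = c(2L, 2L, 4L, 0L))
  meta <- tibble::tibble(sample_id = paste0("s", 1:5),
                         texture = factor(c(rep("foam", 5)),
                                          levels = c("no_foam", "crust",
                                                     "foam")))
  list(counts = counts, meta = meta)
}

test_that("core membership follows the prevalence threshold", {
  fx <- make_core_fixture()
  # o1 present 5/5, o2 4/5, o3 4/5, o4 1/5
  core1 <- core_taxa(fx$counts, fx$meta, "foam", prevalence = 1.0)
  expect_equal(core1$otu_id, "o1")
  core08 <- core_taxa(fx$counts, fx$meta, "foam", prevalence = 0.8)
  expect_setequal(core08$otu_id, c("o1", "o2", "o3"))
  core0 <- core_taxa(fx$counts, fx$meta, "foam", prevalence = 0)
  expect_setequal(core0$otu_id, paste0("o", 1:4))
  expect_error(core_taxa(fx$counts, fx$meta, "foam", prevalence = 1.5),
               "prevalence")
  expect_error(core_taxa(fx$counts, fx$meta, "crust"), "no samples")
})

test_that("core sets are monotone in the prevalence threshold", {
  co <- generate_cohort(small_cohort_config(seed = 51))
  md <- co$metadata
  for (thr in list(c(1.0, 0.8), c(0.8, 0.5))) {
    hi <- core_taxa(co$counts_16s, md, "foam", prevalence = thr[1])
    lo <- core_taxa(co$counts_16s, md, "foam", prevalence = thr[2])
    expect_true(all(hi$otu_id %in% lo$otu_id))
  }
})

test_that("venn partition counts disjoint regions summing to the union", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  vp <- venn_partition(sets)
  get <- function(r) vp$count[vp$region == r]
  expect_equal(get("A&B&C"), 1)          # c
  expect_equal(get("A&B"), 1)            # b
  expect_equal(get("A&C"), 0)
  expect_equal(get("B&C"), 0)
  expect_equal(get("A_only"), 1)         # a
  expect_equal(get("B_only"), 1)         # d
  expect_equal(get("C_only"), 1)         # e
  expect_equal(sum(vp$count), 5)
  # identical sets concentrate in the triple intersection
  vp2 <- venn_partition(list(X = letters[1:4], Y = letters[1:4],
                             Z = letters[1:4]))
  expect_equal(vp2$count[vp2$region == "X&Y&Z"], 4)
  expect_equal(sum(vp2$count), 4)
  # pairwise disjoint sets populate only the unique regions
  vp3 <- venn_partition(list(X = "a", Y = "b", Z = "c"))
  expect_equal(sum(vp3$count[grepl("_only", vp3$region)]), 3)
  expect_equal(sum(vp3$count), 3)
  expect_error(venn_partition(list(A = "a")), "2 or 3")
})

test_that("bootstrap CI is deterministic, ordered, and covers the mean", {
  x <- rep(0.25, 20)
  ci <- bootstrap_ci(x, n_boot = 99, seed = 1)
  expect_equal(ci$lower, 0.25)
  expect_equal(ci$upper, 0.25)
  ci1 <- bootstrap_ci(rnorm(50), n_boot = 199, seed = 5)
  ci2 <- bootstrap_ci(rnorm(50), n_boot = 199, seed = 5)
  # seeded: the resampling (and input draw above) differ, so compare a
  # fixed input instead
  set.seed(9); xx <- rnorm(50)
  ci1 <- bootstrap_ci(xx, n_boot = 199, seed = 5)
  ci2 <- bootstrap_ci(xx, n_boot = 199, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1$lower <= ci1$mean && ci1$mean <= ci1$upper)
  expect_error(bootstrap_ci(1:3), "at least 5")
})

test_that("bootstrap CI coverage is near nominal", {
  set.seed(10)
  hits <- 0
  for (i in 1:200) {
    x <- rnorm(100, 0.2, 0.05)
    ci <- bootstrap_ci(x, n_boot = 199)
    if (ci$lower <= 0.2 && 0.2 <= ci$upper) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.88)
  expect_lte(hits / 200, 0.99)
})

test_that("differential abundance flags the planted enriched taxon", {
  co <- generate_cohort(small_cohort_config(seed = 52, n_farms = 12))
  md <- co$metadata
  ra <- relative_abundance(co$counts_16s)
  da <- differential_abundance(ra, md, bf_threshold = 100, n_boot = 49,
                               seed = 1)
  planted <- da[da$taxon == "OTU16S_0001", ]
  expect_true(planted$significant)
  expect_equal(planted$most_abundant_in, "foam")
  expect_true(all(da$lo_foam <= da$mean_foam & da$mean_foam <= da$hi_foam,
                  na.rm = TRUE))
})

test_that("label shuffling removes differential-abundance calls", {
  co <- generate_cohort(small_cohort_config(seed = 53))
  md <- co$metadata
  set.seed(2)
  md$texture <- sample(md$texture)
  agg <- aggregate_taxonomy(co$counts_16s, co$taxonomy_16s, "genus")
  da <- differential_abundance(relative_abundance(agg), md,
                               bf_threshold = 100, n_boot = 19, seed = 1)
  expect_lte(sum(da$significant), ceiling(0.02 * nrow(da)))
})
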