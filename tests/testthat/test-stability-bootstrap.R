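test_that("lag pairs are within-farm, same-texture, positive-lag only", {
  # one farm, three months, identical compositions -> lags (1,1,2), all 0
  comps <- matrix(rep(c(0.5, 0.3, 0.2), 3), 3)
  ts <- toy_series(comps, farms = rep("F1", 3), months = 1:3,
                   textures = rep("foam", 3))
  lp <- lag_pairs(ts$relabund, ts$metadata, "foam")
  expect_setequal(lp$lag, c(1L, 1L, 2L))
  expect_equal(lp$dissimilarity, rep(0, 3))
  # two farms with one sample each -> no pairs
  ts2 <- toy_series(matrix(c(0.5, 0.5, 0.2, 0.8), 2),
                    farms = c("F1", "F2"), months = c(1, 2),
                    textures = rep("foam", 2))
  expect_equal(nrow(lag_pairs(ts2$relabund, ts2$metadata, "foam")), 0)
  expect_error(lag_pairs(ts2$relabund, ts2$metadata, "crust"), "absent")
})

test_that("drift cohorts show dissimilarity increasing with lag", {
  co <- generate_cohort(cohort_config(
    n_farms = 10, n_months = 12, n_bacterial_otus = 80,
    n_methanogen_otus = 10, mean_depth_16s = 5000, mean_depth_mcra = 1000,
    rare_pool_16s = 150, rare_pool_mcra = 30, missing_rate = 0,
    drift_rate = c(no_foam = 0.12, crust = 0.12, foam = 0.12), seed = 12))
  ra <- relative_abundance(co$counts_16s)
  lp <- lag_pairs(ra, co$metadata, "no_foam")
  per_lag <- tapply(lp$dissimilarity, lp$lag, mean)
  expect_gt(cor(as.numeric(names(per_lag)), per_lag, method = "spearman"), 0)
})

test_that("exponential fit recovers exact and noisy curves", {
  x <- rep(1:12, each = 4)
  y <- 0.3 * exp(0.05 * x)
  fit <- fit_exponential(list(x = x, y = y))
  expect_equal(fit$a_hat, 0.3, tolerance = 1e-6)
  expect_equal(fit$b_hat, 0.05, tolerance = 1e-6)
  # flat series: slope approximately 0
  fit0 <- fit_exponential(list(x = 1:10, y = rep(0.4, 10)))
  expect_equal(fit0$b_hat, 0, tolerance = 1e-6)
  expect_equal(fit0$a_hat, 0.4, tolerance = 1e-6)
  expect_error(fit_exponential(list(x = c(1, 1, 2), y = c(1, 1, 1))),
               "3 distinct")
})

test_that("exponential fit is scale equivariant in y", {
  set.seed(13)
  x <- runif(80, 1, 12)
  y <- 0.2 * exp(0.07 * x) + abs(rnorm(80, 0, 0.01))
  f1 <- fit_exponential(list(x = x, y = y))
  f2 <- fit_exponential(list(x = x, y = 3 * y))
  expect_equal(f2$a_hat / f1$a_hat, 3, tolerance = 1e-4)
  expect_equal(f2$b_hat, f1$b_hat, tolerance = 1e-5)
})

test_that("bootstrap slopes are reproducible and sized as requested", {
  co <- generate_cohort(small_cohort_config(seed = 14))
  ra <- relative_abundance(co$counts_16s)
  md <- co$metadata[co$metadata$sample_id %in% names(ra)[-1], ]
  bs1 <- bootstrap_slopes(ra, md, "no_foam", n_boot = 49, seed = 7)
  bs2 <- bootstrap_slopes(ra, md, "no_foam", n_boot = 49, seed = 7)
  expect_length(bs1$bootstrap_slopes, 49)
  expect_identical(bs1$bootstrap_slopes, bs2$bootstrap_slopes)
  expect_s3_class(tidy(bs1), "tbl_df")
  expect_equal(nrow(tidy(bs1)), 49)
})

test_that("planted drift ordering shows up in bootstrap slopes", {
  co <- generate_cohort(small_cohort_config(
    seed = 15, n_farms = 14, n_months = 10,
    texture_init = c(no_foam = 0.5, crust = 0, foam = 0.5)))
  ra <- relative_abundance(co$counts_16s)
  md <- co$metadata[co$metadata$sample_id %in% names(ra)[-1], ]
  b_no <- bootstrap_slopes(ra, md, "no_foam", n_boot = 99, seed = 1)
  b_fo <- bootstrap_slopes(ra, md, "foam", n_boot = 99, seed = 1)
  expect_gt(median(b_no$bootstrap_slopes), median(b_fo$bootstrap_slopes))
})

test_that("overlap coefficient matches closed forms and edge cases", {
  set.seed(16)
  x <- rnorm(5000)
  expect_gte(overlap_coefficient(x, x), 0.99)
  # disjoint supports far beyond the bandwidth
  expect_lt(overlap_coefficient(runif(100), runif(100) + 100), 0.01)
  # symmetry
  y <- rnorm(500, 2)
  expect_equal(overlap_coefficient(x[1:500], y),
               overlap_coefficient(y, x[1:500]))
  expect_error(overlap_coefficient(rep(1, 20), rnorm(20)), "degenerate")
  expect_error(overlap_coefficient(rnorm(5), rnorm(20)), "at least 10")
})

test_that("stability comparison reports fits, pairwise and pooled overlap", {
  co <- generate_cohort(small_cohort_config(
    seed = 17, n_farms = 10, n_months = 8,
    texture_init = c(no_foam = 1 / 3, crust = 1 / 3, foam = 1 / 3)))
  ra <- relative_abundance(co$counts_16s)
  md <- co$metadata[co$metadata$sample_id %in% names(ra)[-1], ]
  st <- stability_comparison(ra, md, n_boot = 49, seed = 2)
  expect_setequal(names(st$fits), c("no_foam", "crust", "foam"))
  expect_equal(nrow(st$overlap), 3)
  expect_true(all(st$overlap$ovl >= 0 & st$overlap$ovl <= 1))
  expect_true(st$pooled_overlap >= 0 && st$pooled_overlap <= 1)
  gl <- glance(st)
  expect_equal(nrow(gl), 3)
  expect_true(all(c("a_hat", "b_hat", "slope_median") %in% names(gl)))
})
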