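test_that("Spearman handles monotone maps and nulls", {
  x <- seq(-3, 3, length.out = 30)
  expect_equal(spearman(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  expect_equal(spearman(x, 2 * x + 1)$p, 0)
  set.seed(1)
  s <- spearman(runif(1000), runif(1000))
  expect_lt(abs(s$rho), 0.1)
  expect_error(spearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman(1:3, 1:3), "at least 4")
})

test_that("Spearman p matches the t-approximation formula", {
  set.seed(2)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  s <- spearman(x, y)
  tt <- s$rho * sqrt(38 / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tt), 38))
  expect_equal(s$rho, cor(x, y, method = "spearman"))
})

test_that("Hoeffding's D matches a direct double-loop oracle", {
  oracle_d <- oracle_hoeffding_d
  set.seed(3)
  for (rep in 1:5) {
    x <- sample(1:4, 8, replace = TRUE)   # forces ties
    y <- sample(1:4, 8, replace = TRUE)
    expect_equal(hoeffding_d(x, y, n_perm = 9, seed = 1)$D, oracle_d(x, y))
  }
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(hoeffding_d(x, y, n_perm = 9, seed = 1)$D, oracle_d(x, y))
  # perfect functional dependence approaches the maximum of 1
  z <- seq_len(200)
  expect_gt(hoeffding_d(z, z, n_perm = 9)$D, 0.95)
})

test_that("Hoeffding's D finds quadratic dependence Spearman misses", {
  set.seed(4)
  x <- rnorm(200)
  y <- x^2 + rnorm(200, 0, 0.3)
  hd <- hoeffding_d(x, y, n_perm = 199, seed = 1)
  sp <- spearman(x, y)
  expect_lt(hd$p, 0.05)
  expect_gt(sp$p, 0.05)
  # independent pairs: D near zero, p typically large
  x0 <- rnorm(500); y0 <- rnorm(500)
  hd0 <- hoeffding_d(x0, y0, n_perm = 99, seed = 2)
  expect_lt(abs(hd0$D), 0.01)
  expect_gt(hd0$p, 0.05)
  expect_error(hoeffding_d(1:4, 1:4), "at least 5")
})

test_that("Hoeffding's D is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rexp(60); y <- x + rnorm(60, 0, 0.5)
  d1 <- hoeffding_d(x, y, n_perm = 9, seed = 1)$D
  d2 <- hoeffding_d(log(x), exp(y / 5), n_perm = 9, seed = 1)$D
  expect_equal(d1, d2)
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  # monotone in the sorted order
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification rule follows the two-test logic", {
  expect_equal(classify_relationship(0.01, 0.50), "monotonic")
  expect_equal(classify_relationship(0.20, 0.01), "non_monotonic")
  expect_equal(classify_relationship(0.20, 0.20), "none")
  expect_equal(classify_relationship(c(0.04, 0.9), c(0.9, 0.04)),
               c("monotonic", "non_monotonic"))
})

test_that("screen recovers the planted foam-only association", {
  co <- generate_cohort(small_cohort_config(
    seed = 41, n_farms = 12, n_months = 8,
    texture_init = c(no_foam = 1 / 3, crust = 1 / 3, foam = 1 / 3)))
  sc <- screen_correlations(
    co$metadata, tibble::tibble(var_a = "LCFA", var_b = "SCFA"),
    n_perm = 199, seed = 1)
  foam <- sc[sc$group == "foam", ]
  nofoam <- sc[sc$group == "no_foam", ]
  expect_equal(foam$classification, "monotonic")
  expect_equal(nofoam$classification, "none")
  expect_gt(foam$strength, 0.5)
  expect_equal(foam$sign, 1)
})

test_that("screen ranks, skips small groups, and honors top_k = 0", {
  co <- generate_cohort(small_cohort_config(seed = 42))
  md <- co$metadata
  pairs <- tibble::tibble(var_a = c("LCFA", "MPR", "SCFA"),
                          var_b = c("SCFA", "DDGS", "pH"))
  sc0 <- screen_correlations(md, pairs, top_k = 0, n_perm = 49, seed = 1)
  expect_false(any(sc0$top))
  expect_equal(nrow(sc0), 3 * length(unique(md$texture)))
  # a group too small to test is skipped with a reason
  md2 <- md[md$texture != "crust" | seq_len(nrow(md)) <= 5, ]
  md_small <- md2[md2$texture != "crust", ][1:40, ]
  md_small$texture <- factor(as.character(md_small$texture),
                             levels = levels(md$texture))
  md_small$texture[1:3] <- "crust"
  sc1 <- screen_correlations(md_small, pairs[1, ], n_perm = 49, seed = 1)
  crust_row <- sc1[sc1$group == "crust", ]
  expect_match(crust_row$skipped, "n = 3")
  expect_true(is.na(crust_row$classification))
})

test_that("screen edge export carries only significant associations", {
  co <- generate_cohort(small_cohort_config(seed = 43))
  sc <- screen_correlations(
    co$metadata, tibble::tibble(var_a = "LCFA", var_b = "SCFA"),
    n_perm = 199, seed = 1)
  ed <- screen_edges(sc)
  expect_true(all(ed$classification != "none"))
  expect_true(all(c("var_a", "var_b", "sign", "weight", "group") %in%
                    names(ed)))
})
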