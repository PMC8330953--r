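test_that("Bray-Curtis matches the definition on hand cases", {
  m <- cbind(a = c(2, 2), b = c(1, 3), c = c(2, 2), d = c(1, 0))
  rownames(m) <- c("o1", "o2")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0.25)           # (1+1)/(3+5)
  expect_equal(d["a", "c"], 0)              # identical
  e <- cbind(x = c(1, 0), y = c(0, 1))
  expect_equal(as.numeric(bray_curtis(e)), 1)  # disjoint supports
  expect_error(bray_curtis(cbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("Bray-Curtis agrees with vegan and is rescaling invariant", {
  skip_if_not_installed("vegan")
  set.seed(42)
  m <- matrix(rpois(30 * 12, 8), 30, 12,
              dimnames = list(NULL, paste0("s", 1:12)))
  d <- bray_curtis(m)
  dv <- vegan::vegdist(t(m), method = "bray")
  expect_lt(max(abs(as.matrix(d) - as.matrix(dv))), 1e-12)
  # a common positive rescaling of the samples leaves BC unchanged
  ra <- sweep(m, 2, colSums(m), "/")
  expect_lt(max(abs(as.matrix(bray_curtis(ra)) -
                      as.matrix(bray_curtis(3.7 * ra)))), 1e-12)
})

test_that("PERMANOVA separates constructed groups and matches adonis2", {
  skip_if_not_installed("vegan")
  set.seed(7)
  base <- matrix(runif(20 * 10, 0.5, 1.5), 20, 10)
  m <- cbind(pmax(base + matrix(rnorm(200, 0, 0.01), 20), 0),
             pmax(base + 10 + matrix(rnorm(200, 0, 0.01), 20), 0))
  colnames(m) <- paste0("s", 1:20)
  md <- tibble::tibble(sample_id = colnames(m),
                       grp = rep(c("A", "B"), each = 10))
  d <- bray_curtis(m)
  fit <- permanova(md, d, grp, n_perm = 199, seed = 1)
  expect_gt(fit$R2, 0.95)
  expect_equal(fit$p_value, 1 / 200)
  av <- vegan::adonis2(d ~ grp, data = md, permutations = 99)
  expect_equal(fit$R2, av$R2[1], tolerance = 1e-10)
  expect_equal(fit$pseudo_F, av$F[1], tolerance = 1e-10)
})

test_that("exact PERMANOVA p equals brute-force enumeration", {
  set.seed(3)
  m <- matrix(runif(8 * 6), 8, 6, dimnames = list(NULL, paste0("s", 1:6)))
  md <- tibble::tibble(sample_id = colnames(m),
                       grp = rep(c("A", "B"), each = 3))
  d <- bray_curtis(m)
  fit <- permanova(md, d, grp, method = "exact")

  # oracle: enumerate all C(6,3) = 20 assignments of labels to positions
  D2 <- as.matrix(d)^2
  f_of <- function(lab) {
    ss_tot <- sum(D2) / 12
    ssw <- 0
    for (g in unique(lab)) {
      i <- which(lab == g)
      ssw <- ssw + sum(D2[i, i]) / (2 * length(i))
    }
    ((ss_tot - ssw) / 1) / (ssw / 4)
  }
  obs <- f_of(md$grp)
  fs <- apply(combn(6, 3), 2, function(ii) {
    lab <- rep("B", 6); lab[ii] <- "A"; f_of(lab)
  })
  p_oracle <- mean(fs >= obs - 1e-12)
  expect_equal(fit$p_value, p_oracle)
  expect_equal(fit$n_permutations, 20)
})

test_that("farm-stratified permutations guard against pseudoreplication", {
  # texture constant within farm: stratified PERMANOVA must not find signal
  lev <- c("no_foam", "crust", "foam")
  tm <- diag(3)
  dimnames(tm) <- list(lev, lev)
  co <- generate_cohort(small_cohort_config(
    seed = 21, texture_transition = tm,
    texture_init = c(no_foam = 0.5, crust = 0, foam = 0.5)))
  ra <- relative_abundance(co$counts_16s)
  md <- co$metadata
  d <- bray_curtis(ra)
  fit <- permanova(md, d, texture, strata = farm, n_perm = 99, seed = 1)
  expect_gt(fit$p_value, 0.9)
})

test_that("PERMANOVA R2 does not depend on the permutations", {
  co <- generate_cohort(small_cohort_config(seed = 6))
  d <- bray_curtis(relative_abundance(co$counts_16s))
  f1 <- permanova(co$metadata, d, texture, n_perm = 29, seed = 1)
  f2 <- permanova(co$metadata, d, texture, n_perm = 199, seed = 99)
  expect_equal(f1$R2, f2$R2)
  f3 <- permanova(co$metadata, d, texture, n_perm = 199, seed = 99)
  expect_equal(f2$p_value, f3$p_value)
})

test_that("NMDS recovers a planar configuration with near-zero stress", {
  set.seed(5)
  pts <- matrix(rnorm(20), 10, 2)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("s", 1:10)
  fit <- nmds(d, k = 2, n_restarts = 2, max_iter = 500, tol = 1e-12, seed = 1)
  expect_lte(fit$stress, 0.01)
  # stress never increases along the winning run
  expect_true(all(diff(fit$stress_trace) <= 1e-8))
  # determinism
  fit2 <- nmds(d, k = 2, n_restarts = 2, max_iter = 500, tol = 1e-12, seed = 1)
  expect_identical(fit$coordinates, fit2$coordinates)
})

test_that("NMDS stress is monotone in k and invariant to rigid motions", {
  co <- generate_cohort(cohort_config(
    n_farms = 4, n_months = 3, n_bacterial_otus = 40, n_methanogen_otus = 10,
    mean_depth_16s = 2000, mean_depth_mcra = 500, rare_pool_16s = 60,
    rare_pool_mcra = 20, missing_rate = 0, seed = 8))
  d <- bray_curtis(relative_abundance(co$counts_16s))
  f2 <- nmds(d, k = 2, n_restarts = 3, max_iter = 300, seed = 2)
  f5 <- nmds(d, k = 8, n_restarts = 3, max_iter = 300, seed = 2)
  expect_lte(f5$stress, f2$stress + 1e-6)
  # rotating/translating coordinates leaves configured stress unchanged
  x <- as.matrix(f2$coordinates[, -1])
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  cd1 <- dist(x)
  cd2 <- dist(sweep(x %*% rot, 2, c(3, -1), "+"))
  expect_lt(max(abs(cd1 - cd2)), 1e-10)
  expect_error(nmds(d, k = 0), "k must be")
})

test_that("environmental surface fit recovers quadratic structure", {
  set.seed(9)
  co <- matrix(rnorm(400), 200, 2)
  ordf <- structure(list(coordinates = dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", 1:200)),
    tibble::as_tibble(`colnames<-`(co, c("NMDS1", "NMDS2"))))),
    class = "nmds_fit")
  env <- 1 + 2 * co[, 1] - co[, 2] + 0.5 * co[, 1]^2 + co[, 1] * co[, 2]
  fit <- fit_env_surface(ordf, env)
  expect_equal(fit$R2, 1, tolerance = 1e-9)
  # independent env: R2 near zero
  fit0 <- fit_env_surface(ordf, rnorm(200))
  expect_lt(fit0$R2, 0.06)
  # constant env: R2 defined as 0
  fitc <- fit_env_surface(ordf, rep(2.5, 200))
  expect_equal(fitc$R2, 0)
})
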