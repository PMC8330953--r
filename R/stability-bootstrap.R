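#' Within-farm dissimilarity versus time lag
#'
#' For every unordered pair of same-texture samples collected from the same
#' farm, emits the time lag in months and the Bray-Curtis dissimilarity
#' between the two communities. Pairing is restricted to within-farm pairs
#' because between-farm dissimilarity is dominated by the farm effect and
#' would swamp the temporal signal; zero-lag pairs are excluded.
#'
#' @param relabund Wide relative-abundance tibble (see
#'   [relative_abundance()]).
#' @param metadata Sample metadata with `sample_id`, `farm`, `month` and
#'   the grouping column.
#' @param group Texture group to analyse (e.g. `"foam"`).
#' @param group_col Grouping column name.
#' @return A tibble with `farm`, `sample_a`, `sample_b`, `lag`,
#'   `dissimilarity`.
#' @export
lag_pairs <- function(relabund, metadata, group, group_col = "texture") {
  if (!group %in% as.character(metadata[[group_col]])) {
    abort(sprintf("group '%s' absent from metadata", group))
  }
  sub <- metadata[as.character(metadata[[group_col]]) == group &
                    !is.na(metadata[[group_col]]), ]
  ids <- intersect(names(relabund)[-1], sub$sample_id)
  sub <- sub[match(ids, sub$sample_id), ]
  if (nrow(sub) < 2) {
    return(tibble::tibble(farm = character(), sample_a = character(),
                          sample_b = character(), lag = integer(),
                          dissimilarity = double()))
  }
  d <- as.matrix(bray_curtis(relabund[, c(names(relabund)[1], ids)]))
  out <- purrr::map(split(seq_len(nrow(sub)), sub$farm), function(ii) {
    if (length(ii) < 2) return(NULL)
    cmb <- combn(ii, 2)
    lag <- abs(sub$month[cmb[1, ]] - sub$month[cmb[2, ]])
    keep <- lag > 0
    tibble::tibble(farm = sub$farm[cmb[1, keep]],
                   sample_a = sub$sample_id[cmb[1, keep]],
                   sample_b = sub$sample_id[cmb[2, keep]],
                   lag = as.integer(lag[keep]),
                   dissimilarity = d[cbind(cmb[1, keep], cmb[2, keep])])
  })
  dplyr::bind_rows(out)
}

#' Fit an exponential dissimilarity-time curve
#'
#' Nonlinear least squares of `y = a * exp(b * x)`; a larger slope `b`
#' means communities decay apart faster, i.e. are less stable. Initialized
#' from the log-linear regression of `log(y + 1e-6)` on `x`. If the
#' nonlinear fit fails to converge the error carries the log-linear
#' fallback coefficients.
#'
#' @param pairs Data frame with columns `lag` (or `x`) and `dissimilarity`
#'   (or `y`); needs >= 3 distinct x values and non-negative y.
#' @return A list with `a_hat`, `b_hat`, `n` and the `nls` fit object.
#' @export
fit_exponential <- function(pairs) {
  x <- pairs$lag %||% pairs$x
  y <- pairs$dissimilarity %||% pairs$y
  if (length(unique(x)) < 3) abort("need at least 3 distinct lags")
  if (any(y < 0)) abort("dissimilarities must be non-negative")
  ll <- lm(log(y + 1e-6) ~ x)
  rss <- function(s) sum((y - s$a * exp(s$b * x))^2)
  start <- list(a = exp(coef(ll)[[1]]), b = coef(ll)[[2]])
  flat <- list(a = mean(y), b = 0)
  if (rss(flat) < rss(start)) start <- flat
  attempt <- function(s) {
    tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x), start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  fit <- attempt(start)
  if (inherits(fit, "error")) {
    # a start that already fits (near-)exactly makes the gradient singular;
    # it is then itself the least-squares solution
    if (rss(start) <= 1e-8 * (sum(y^2) + 1e-12)) {
      return(list(a_hat = start$a, b_hat = start$b, n = length(x),
                  fit = NULL))
    }
    fit <- attempt(list(a = start$a, b = start$b + 0.01))
    if (inherits(fit, "error")) {
      abort(sprintf(
        "exponential fit failed (%s); log-linear fallback a=%.4g b=%.4g",
        conditionMessage(fit), start$a, start$b))
    }
  }
  cf <- coef(fit)
  list(a_hat = cf[["a"]], b_hat = cf[["b"]], n = length(x), fit = fit)
}

#' Bootstrap distribution of community-stability slopes
#'
#' Resamples the group's samples with replacement (each resampled sample
#' keeps its farm identity), rebuilds the within-farm lag pairs, and refits
#' the exponential curve, giving a bootstrap distribution of the slope `b`.
#' Replicates whose resample cannot be fit (fewer than 3 distinct lags, or
#' non-convergence) are redrawn, up to a 20% failure budget.
#'
#' @inheritParams lag_pairs
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @return An object of class `stability_fit`: `group`, `pairs_used`,
#'   `a_hat`, `b_hat` (full-data fit), `bootstrap_slopes` (length
#'   `n_boot`), `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_slopes <- function(relabund, metadata, group,
                             group_col = "texture", n_boot = 999,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- metadata[as.character(metadata[[group_col]]) == group &
                    !is.na(metadata[[group_col]]), ]
  ids <- intersect(names(relabund)[-1], sub$sample_id)
  sub <- sub[match(ids, sub$sample_id), ]
  n <- nrow(sub)
  if (n < 4) abort("too few samples in group for bootstrapping")
  dmat <- as.matrix(bray_curtis(relabund[, c(names(relabund)[1], ids)]))
  farm <- sub$farm
  month <- sub$month

  pairs_from <- function(idx) {
    cmb <- combn(seq_along(idx), 2)
    i <- idx[cmb[1, ]]; j <- idx[cmb[2, ]]
    same <- farm[i] == farm[j]
    lag <- abs(month[i] - month[j])
    keep <- same & lag > 0 & i != j
    list(x = lag[keep], y = dmat[cbind(i, j)][keep])
  }

  full <- pairs_from(seq_len(n))
  full_fit <- fit_exponential(list(x = full$x, y = full$y))

  slopes <- numeric(0)
  failed <- 0L
  max_fail <- ceiling(0.2 * n_boot)
  while (length(slopes) < n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    pr <- pairs_from(idx)
    b <- tryCatch({
      if (length(unique(pr$x)) < 3) stop("degenerate resample")
      fit_exponential(list(x = pr$x, y = pr$y))$b_hat
    }, error = function(e) NA_real_)
    if (is.na(b)) {
      failed <- failed + 1L
      if (failed > max_fail) {
        abort(sprintf("more than 20%% of bootstrap replicates failed (%d)",
                      failed))
      }
    } else {
      slopes <- c(slopes, b)
    }
  }
  structure(list(group = group, pairs_used = length(full$x),
                 a_hat = full_fit$a_hat, b_hat = full_fit$b_hat,
                 bootstrap_slopes = slopes, n_boot = n_boot,
                 n_failed = failed, seed = seed),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  q <- quantile(x$bootstrap_slopes, c(0.025, 0.5, 0.975))
  cat(sprintf(
    "Stability fit [%s]: y = %.4g * exp(%.4g x), %d pairs\n", x$group,
    x$a_hat, x$b_hat, x$pairs_used))
  cat(sprintf("  bootstrap slope median %.4g (95%% %.4g..%.4g, %d reps)\n",
              q[2], q[1], q[3], x$n_boot))
  invisible(x)
}

#' Overlap coefficient of two empirical distributions
#'
#' `OVL = integral of min(f_a, f_b)`, with the densities estimated by
#' Gaussian kernels (Silverman's rule-of-thumb bandwidth) on a shared grid
#' spanning both samples, integrated by the trapezoid rule. 1 means
#' identical distributions, 0 disjoint ones.
#'
#' @param slopes_a,slopes_b Numeric vectors (length >= 10, non-degenerate).
#' @param n_grid Grid resolution (>= 512).
#' @return Overlap in `[0, 1]`.
#' @export
overlap_coefficient <- function(slopes_a, slopes_b, n_grid = 1024) {
  if (length(slopes_a) < 10 || length(slopes_b) < 10) {
    abort("need at least 10 values per sample")
  }
  if (sd(slopes_a) == 0 || sd(slopes_b) == 0) {
    abort("degenerate (zero-variance) vector")
  }
  bw_a <- stats::bw.nrd0(slopes_a)
  bw_b <- stats::bw.nrd0(slopes_b)
  lo <- min(slopes_a, slopes_b) - 3 * max(bw_a, bw_b)
  hi <- max(slopes_a, slopes_b) + 3 * max(bw_a, bw_b)
  fa <- density(slopes_a, bw = bw_a, from = lo, to = hi, n = n_grid)
  fb <- density(slopes_b, bw = bw_b, from = lo, to = hi, n = n_grid)
  min(max(trapezoid(fa$x, pmin(fa$y, fb$y)), 0), 1)
}

#' Compare community stability across texture groups
#'
#' Runs [bootstrap_slopes()] for each texture present, then compares slope
#' distributions by [overlap_coefficient()]: all pairwise comparisons, plus
#' the pooled comparison of the no-foam slopes against the crust and foam
#' slopes combined.
#'
#' @inheritParams bootstrap_slopes
#' @param groups Textures to include (default: all present).
#' @param min_pairs Groups with fewer within-farm lag pairs than this are
#'   skipped (with a recorded reason) rather than fitted: a two-parameter
#'   decay curve on a handful of pairs is not meaningful.
#' @return A list of class `stability_comparison` with `fits` (named list
#'   of `stability_fit`), `overlap` (tibble of pairwise OVLs),
#'   `pooled_overlap` (no-foam vs pooled others, `NA` if not computable)
#'   and `skipped` (tibble of skipped groups with reasons).
#' @export
stability_comparison <- function(relabund, metadata, groups = NULL,
                                 group_col = "texture", n_boot = 999,
                                 min_pairs = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- groups %||%
    intersect(texture_levels(), unique(as.character(metadata[[group_col]])))
  skipped <- tibble::tibble(group = character(), reason = character())
  fits <- list()
  for (gv in groups) {
    lp <- lag_pairs(relabund, metadata, gv, group_col = group_col)
    if (nrow(lp) < min_pairs) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        group = gv, reason = sprintf("only %d lag pairs < %d", nrow(lp),
                                     min_pairs)))
      next
    }
    fit <- tryCatch(
      bootstrap_slopes(relabund, metadata, gv, group_col = group_col,
                       n_boot = n_boot),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      skipped <- dplyr::bind_rows(skipped,
                                  tibble::tibble(group = gv, reason = fit))
    } else {
      fits[[gv]] <- fit
    }
  }
  groups <- names(fits)
  cmb <- if (length(groups) >= 2) combn(groups, 2) else
    matrix(character(), 2, 0)
  ovl <- purrr::map(seq_len(ncol(cmb)), function(i) {
    tibble::tibble(group_a = cmb[1, i], group_b = cmb[2, i],
                   ovl = overlap_coefficient(
                     fits[[cmb[1, i]]]$bootstrap_slopes,
                     fits[[cmb[2, i]]]$bootstrap_slopes))
  })
  pooled <- NA_real_
  others <- setdiff(groups, "no_foam")
  if ("no_foam" %in% groups && length(others) >= 1) {
    pooled <- overlap_coefficient(
      fits[["no_foam"]]$bootstrap_slopes,
      unlist(lapply(fits[others], `[[`, "bootstrap_slopes")))
  }
  structure(list(fits = fits, overlap = dplyr::bind_rows(ovl),
                 pooled_overlap = pooled, skipped = skipped),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  for (f in x$fits) print(f)
  if (nrow(x$skipped)) {
    cat("skipped:", paste(x$skipped$group, "-", x$skipped$reason,
                          collapse = "; "), "\n")
  }
  if (nrow(x$overlap)) print(x$overlap)
  if (!is.na(x$pooled_overlap)) {
    cat(sprintf("no-foam vs pooled crust+foam OVL = %.4f\n",
                x$pooled_overlap))
  }
  invisible(x)
}
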