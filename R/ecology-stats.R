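#' Bray-Curtis dissimilarity matrix
#'
#' Computes `d(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` between
#' all pairs of samples. On relative-abundance input the result is invariant
#' to any common positive rescaling of a sample.
#'
#' @param abund Wide tibble (first column taxon ids, one column per sample)
#'   or a numeric matrix (taxa x samples) of non-negative abundances; no
#'   sample may be all-zero.
#' @return A [stats::dist] object labelled with sample ids
#'   (`method = "bray"`).
#' @export
bray_curtis <- function(abund) {
  m <- if (is.data.frame(abund)) counts_to_matrix(abund) else as.matrix(abund)
  if (any(m < 0)) abort("abundances must be non-negative")
  s <- colSums(m)
  if (any(s == 0)) abort("all-zero sample: Bray-Curtis undefined")
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    cmin <- colSums(pmin(m[, j, drop = FALSE], m[, i]))
    d[j, i] <- 1 - 2 * cmin / (s[i] + s[j])
  }
  out <- stats::as.dist(d)
  attr(out, "Labels") <- colnames(m)
  attr(out, "method") <- "bray"
  out
}

all_multiset_perms <- function(labels) {
  labels <- as.character(labels)
  rec <- function(pool) {
    if (length(pool) == 1) return(list(pool))
    out <- list()
    for (u in unique(pool)) {
      rest <- pool[-match(u, pool)]
      for (tail in rec(rest)) out[[length(out) + 1]] <- c(u, tail)
    }
    out
  }
  do.call(rbind, rec(labels))
}

permute_within <- function(n, strata) {
  idx <- seq_len(n)
  for (s in split(seq_len(n), strata)) {
    idx[s] <- if (length(s) > 1) s[sample.int(length(s))] else s
  }
  idx
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix using the squared-distance
#' partition: `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum over
#' groups of within-group squared distances / group size`, and
#' `pseudo-F = (SS_between / (a-1)) / (SS_within / (N-a))`. Significance is
#' assessed by permuting group labels; when `strata` is given (e.g. farms
#' treated as experimental blocks) labels are permuted only within each
#' stratum, guarding against pseudoreplication from repeated sampling of
#' the same farm. The p-value uses the add-one correction
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` and so is never exactly 0;
#' with `method = "exact"` all distinct label arrangements are enumerated
#' instead and `p` is the exact proportion with `F >= F_obs`.
#'
#' @param data Data frame with one row per sample, aligned to `d` via
#'   `sample_col`.
#' @param d A [stats::dist] (e.g. from [bray_curtis()]) with sample-id
#'   labels.
#' @param group Column in `data` (unquoted) defining the groups.
#' @param strata Optional column (unquoted) defining permutation blocks.
#' @param n_perm Number of permutations for `method = "sampled"`.
#' @param method `"sampled"` (default) or `"exact"` (full enumeration,
#'   small n only).
#' @param sample_col Name of the sample-id column in `data`.
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `permanova_fit`; see [tidy()] and [glance()].
#' @export
permanova <- function(data, d, group, strata = NULL, n_perm = 999,
                      method = c("sampled", "exact"),
                      sample_col = "sample_id", seed = NULL) {
  method <- match.arg(method)
  labs <- attr(d, "Labels")
  idx <- match(labs, data[[sample_col]])
  if (anyNA(idx)) abort("distance labels missing from data")
  data <- data[idx, ]
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  if (anyNA(g)) abort("missing group labels")
  a <- nlevels(g)
  if (a < 2) abort("need at least 2 groups")
  sq <- rlang::enquo(strata)
  st <- if (rlang::quo_is_null(sq)) NULL else dplyr::pull(data, !!sq)
  gname <- rlang::as_label(rlang::enquo(group))
  sname <- if (is.null(st)) NA_character_ else rlang::as_label(sq)
  if (!is.null(seed)) set.seed(seed)

  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  ss_total <- sum(D2) / (2 * n)
  M0 <- model.matrix(~ g - 1)
  ng <- colSums(M0)
  f_stat <- function(M) {
    ssw <- sum(colSums(M * (D2 %*% M)) / (2 * ng))
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(M0)
  ssw_obs <- sum(colSums(M0 * (D2 %*% M0)) / (2 * ng))
  r2 <- (ss_total - ssw_obs) / ss_total

  if (method == "exact") {
    if (n > 10) abort("exact enumeration limited to n <= 10")
    if (!is.null(st)) abort("exact enumeration does not support strata")
    arr <- all_multiset_perms(g)
    fp <- apply(arr, 1, function(lab) {
      f_stat(model.matrix(~ factor(lab, levels = levels(g)) - 1))
    })
    p <- mean(fp >= f_obs - 1e-12)
    n_used <- nrow(arr)
  } else {
    fp <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pidx <- if (is.null(st)) sample.int(n) else permute_within(n, st)
      fp[b] <- f_stat(M0[pidx, , drop = FALSE])
    }
    p <- (1 + sum(fp >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }

  structure(list(pseudo_F = f_obs, R2 = r2, p_value = p,
                 n_permutations = n_used, method = method,
                 grouping = gname, strata = sname,
                 df = c(between = a - 1, within = n - a),
                 n = n, group_sizes = setNames(as.integer(ng), levels(g)),
                 perm_F = fp),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA: %s%s\n", x$grouping,
              if (!is.na(x$strata)) paste0(" (strata: ", x$strata, ")") else ""))
  cat(sprintf("  pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d %s permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations, x$method))
  invisible(x)
}

# pool-adjacent-violators disparities under the primary tie approach:
# within blocks of tied dissimilarities, configuration distances are sorted
# ascending, so ties are free to take unequal fitted values
monotone_disparities <- function(dv, cd) {
  o <- order(dv, cd)
  fit <- isoreg(cd[o])$yf
  dhat <- numeric(length(dv))
  dhat[o] <- fit
  dhat
}

nmds_engine <- function(dm, x0, max_iter, tol) {
  n <- nrow(dm)
  dv <- dm[lower.tri(dm)]
  x <- x0
  trace <- numeric(0)
  stress <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cdm <- as.matrix(dist(x))
    cd <- cdm[lower.tri(cdm)]
    dhat <- monotone_disparities(dv, cd)
    s2 <- sum((cd - dhat)^2) / sum(cd^2)
    new_stress <- sqrt(max(s2, 0))
    trace <- c(trace, new_stress)
    if (is.finite(stress) && stress - new_stress < tol) {
      stress <- min(stress, new_stress)
      converged <- TRUE
      break
    }
    stress <- new_stress
    # Guttman transform
    ratio <- matrix(0, n, n)
    nz <- cdm > 0
    dhm <- matrix(0, n, n)
    dhm[lower.tri(dhm)] <- dhat
    dhm <- dhm + t(dhm)
    ratio[nz] <- dhm[nz] / cdm[nz]
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x <- (b %*% x) / n
  }
  list(x = x, stress = stress, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling
#'
#' Ordains samples in `k` dimensions by minimizing Kruskal's stress-1,
#' `sqrt(sum((d_config - dhat)^2) / sum(d_config^2))`, where `dhat` is a
#' monotone (isotonic) regression of configuration distances on the input
#' dissimilarities (primary tie treatment). Optimization alternates
#' isotonic fitting with Guttman-transform (SMACOF) configuration updates;
#' the best of `n_restarts` starts (classical-scaling start plus random
#' starts) is returned.
#'
#' @param d A [stats::dist] with sample labels.
#' @param k Number of ordination dimensions.
#' @param n_restarts Number of starts (the first is classical scaling).
#' @param max_iter,tol Iteration cap and stress-decrease convergence
#'   tolerance per start.
#' @param seed Optional integer seed (random starts).
#' @return An object of class `nmds_fit` with `coordinates` (tibble:
#'   `sample_id`, `NMDS1..NMDSk`), `stress`, `converged`, `n_restarts`,
#'   and the per-iteration `stress_trace` of the winning start.
#' @export
nmds <- function(d, k = 2, n_restarts = 4, max_iter = 200, tol = 1e-7,
                 seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (k < 1) abort("k must be >= 1")
  if (k >= n) abort("k must be smaller than the number of samples")
  if (!is.null(seed)) set.seed(seed)
  starts <- vector("list", n_restarts)
  cs <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(cs) < k) cs <- cbind(cs, matrix(rnorm(n * (k - ncol(cs)), 0, 1e-4), n))
  starts[[1]] <- cs
  if (n_restarts > 1) {
    for (r in 2:n_restarts) {
      starts[[r]] <- matrix(rnorm(n * k), n, k) * mean(dm) / 2
    }
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmds_engine(dm, starts[[r]], max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$x
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(sample_id = attr(d, "Labels") %||%
                       as.character(seq_len(n))),
      tibble::as_tibble(coords)),
    stress = best$stress, k = k, n_restarts = n_restarts,
    converged = best$converged, stress_trace = best$trace),
    class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS: k = %d, stress = %.4f (%sconverged, best of %d starts)\n",
              x$k, x$stress, if (x$converged) "" else "not ", x$n_restarts))
  invisible(x)
}

#' Fit an environmental variable as a surface over an ordination
#'
#' Least-squares fit of an environmental variable (e.g. methane production
#' rate) on a full quadratic polynomial in the ordination coordinates: the
#' deterministic contour-fitting stand-in used to overlay measured
#' covariates on community ordinations. Samples with missing values are
#' dropped first. For a constant variable the R-squared is defined as 0.
#'
#' @param ord An `nmds_fit`.
#' @param env Numeric vector aligned to the ordination's samples.
#' @return An object of class `env_surface_fit` with `R2`, `fitted` values,
#'   and the underlying `lm` fit.
#' @export
fit_env_surface <- function(ord, env) {
  co <- as.matrix(ord$coordinates[, -1, drop = FALSE])
  if (length(env) != nrow(co)) abort("env must align with ordination samples")
  ok <- is.finite(env)
  co <- co[ok, , drop = FALSE]
  y <- env[ok]
  xx <- stats::poly(co, degree = 2, raw = TRUE)
  if (nrow(co) <= ncol(xx) + 1) abort("fewer samples than polynomial terms")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    return(structure(list(R2 = 0, fitted = y, model = NULL,
                          sample_id = ord$coordinates$sample_id[ok]),
                     class = "env_surface_fit"))
  }
  fit <- lm(y ~ xx)
  r2 <- 1 - sum(resid(fit)^2) / sst
  structure(list(R2 = min(max(r2, 0), 1), fitted = unname(fitted(fit)),
                 model = fit, sample_id = ord$coordinates$sample_id[ok]),
            class = "env_surface_fit")
}

#' @export
print.env_surface_fit <- function(x, ...) {
  cat(sprintf("Quadratic environmental surface: R2 = %.4f (n = %d)\n",
              x$R2, length(x$fitted)))
  invisible(x)
}
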