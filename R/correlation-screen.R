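#' Spearman rank correlation with t-approximation p-value
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value comes from `t = rho * sqrt((n-2) / (1-rho^2))`
#' with `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are
#'   dropped; n >= 4 required.
#' @return A list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: rho undefined")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

hoeffding_stat <- function(lx, ex, ly, ey, R, S, n) {
  Q <- colSums(lx & ly) + 0.5 * colSums(ex & ly) +
    0.5 * colSums(lx & ey) + 0.25 * (colSums(ex & ey) - 1)
  A <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  B <- sum((R - 2) * (S - 2) * Q)
  CC <- sum(Q * (Q - 1))
  30 * (A - 2 * (n - 2) * B + (n - 2) * (n - 3) * CC) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Hoeffding's D test of dependence
#'
#' Rank-based statistic sensitive to any form of dependence, including
#' non-monotonic relationships invisible to Spearman's rho. With mid-ranks
#' `R_i`, `S_i` of `x_i`, `y_i` and bivariate rank
#' `Q_i = #[x_j < x_i & y_j < y_i]` (half-corrections for ties on either
#' coordinate, quarter for both),
#' `D = 30 (A - 2(n-2) B + (n-2)(n-3) C) / (n(n-1)(n-2)(n-3)(n-4))` where
#' `A = sum (R-1)(R-2)(S-1)(S-2)`, `B = sum (R-2)(S-2) Q`,
#' `C = sum Q(Q-1)`. D is scaled so independence gives values near 0 and a
#' perfect functional relationship gives 1. The p-value is obtained by
#' permuting `y` (seeded), with the add-one correction.
#'
#' @param x,y Paired numeric vectors, n >= 5 complete pairs.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Optional integer seed.
#' @return A list with `D`, `p` and `n`.
#' @export
hoeffding_d <- function(x, y, n_perm = 199, seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) abort("Hoeffding's D needs at least 5 complete pairs")
  if (!is.null(seed)) set.seed(seed)
  R <- rank(x); S <- rank(y)
  lx <- outer(x, x, "<"); ex <- outer(x, x, "==")
  ly <- outer(y, y, "<"); ey <- outer(y, y, "==")
  d_obs <- hoeffding_stat(lx, ex, ly, ey, R, S, n)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    dp <- hoeffding_stat(lx, ex, ly[p, p], ey[p, p], R, S[p], n)
    if (dp >= d_obs - 1e-14) exceed <- exceed + 1L
  }
  list(D = d_obs, p = (1 + exceed) / (1 + n_perm), n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the raw p-values ascending and returns
#' `p_adj_(i) = min_{j >= i} min(1, p_(j) * m / j)` in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Classify a relationship from adjusted p-values
#'
#' Monotonic if the adjusted Spearman p is below `alpha`; non-monotonic if
#' the adjusted Hoeffding p is below `alpha` while the adjusted Spearman p
#' is not; otherwise none.
#'
#' @param spearman_p_adj,hoeffding_p_adj Adjusted p-values in `[0, 1]`
#'   (vectorized).
#' @param alpha Significance level.
#' @return Character vector: `"monotonic"`, `"non_monotonic"` or `"none"`.
#' @export
classify_relationship <- function(spearman_p_adj, hoeffding_p_adj,
                                  alpha = 0.05) {
  dplyr::case_when(
    spearman_p_adj < alpha ~ "monotonic",
    hoeffding_p_adj < alpha ~ "non_monotonic",
    TRUE ~ "none"
  )
}

#' Correlation-classification screen across texture groups
#'
#' Tests the requested variable pairs within each texture group with both
#' Spearman's correlation (monotonic) and Hoeffding's D (any dependence),
#' adjusts p-values by Benjamini-Hochberg within each (group, test) family,
#' classifies each pair ([classify_relationship()]) and ranks the
#' strongest associations per group (|rho| for monotonic pairs, D for
#' non-monotonic; ranks are within classification type since the two
#' statistics are not on one scale).
#'
#' @param data Tibble with one row per sample: the grouping column plus all
#'   variables named in `pairs`. Variables may be metadata measurements or
#'   taxa relative abundances.
#' @param pairs Two-column data frame (or tibble) of `var_a`, `var_b`.
#' @param group_col Grouping column name (default `"texture"`).
#' @param alpha Significance level applied to adjusted p-values.
#' @param top_k How many strongest associations to flag per group (by
#'   within-type rank); `0` flags none but keeps all records.
#' @param n_perm Permutations for the Hoeffding p-value.
#' @param min_n Minimum complete pairs required in a group; smaller groups
#'   are skipped with a reason.
#' @param seed Optional integer seed.
#' @return A tibble of class `correlation_screen`: one row per
#'   (group, pair) with `n`, `spearman_rho`, `spearman_p`,
#'   `spearman_p_adj`, `hoeffding_D`, `hoeffding_p`, `hoeffding_p_adj`,
#'   `classification`, `strength`, `sign`, `top` flag, and `skipped`
#'   reason where applicable.
#' @export
screen_correlations <- function(data, pairs, group_col = "texture",
                                alpha = 0.05, top_k = 5, n_perm = 199,
                                min_n = 8, seed = NULL) {
  stopifnot(all(c("var_a", "var_b") %in% names(pairs)))
  vars <- unique(c(pairs$var_a, pairs$var_b))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(paste("pair variables absent from data:",
                paste(missing_vars, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  groups <- levels(factor(data[[group_col]]))
  out <- purrr::map(groups, function(gv) {
    sub <- data[data[[group_col]] == gv & !is.na(data[[group_col]]), ]
    recs <- purrr::pmap(pairs[, c("var_a", "var_b")], function(var_a, var_b) {
      x <- sub[[var_a]]; y <- sub[[var_b]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      base <- tibble::tibble(group = gv, var_a = var_a, var_b = var_b, n = n)
      if (n < min_n || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        reason <- if (n < min_n) sprintf("n = %d < %d", n, min_n) else
          "constant variable"
        return(dplyr::mutate(base, spearman_rho = NA_real_,
                             spearman_p = NA_real_, hoeffding_D = NA_real_,
                             hoeffding_p = NA_real_, skipped = reason))
      }
      sp <- spearman(x[ok], y[ok])
      hd <- hoeffding_d(x[ok], y[ok], n_perm = n_perm)
      dplyr::mutate(base, spearman_rho = sp$rho, spearman_p = sp$p,
                    hoeffding_D = hd$D, hoeffding_p = hd$p,
                    skipped = NA_character_)
    })
    gtab <- dplyr::bind_rows(recs)
    tested <- is.na(gtab$skipped)
    gtab$spearman_p_adj <- NA_real_
    gtab$hoeffding_p_adj <- NA_real_
    # BH within this group, separately per test family
    gtab$spearman_p_adj[tested] <- bh_adjust(gtab$spearman_p[tested])
    gtab$hoeffding_p_adj[tested] <- bh_adjust(gtab$hoeffding_p[tested])
    gtab$classification <- ifelse(
      tested,
      classify_relationship(gtab$spearman_p_adj, gtab$hoeffding_p_adj, alpha),
      NA_character_)
    gtab$strength <- dplyr::case_when(
      gtab$classification == "monotonic" ~ abs(gtab$spearman_rho),
      gtab$classification == "non_monotonic" ~ gtab$hoeffding_D,
      TRUE ~ NA_real_)
    gtab$sign <- dplyr::if_else(gtab$classification == "monotonic",
                                sign(gtab$spearman_rho), NA_real_)
    gtab <- gtab %>%
      dplyr::group_by(.data$classification) %>%
      dplyr::mutate(rank_in_type = dplyr::if_else(
        .data$classification %in% c("monotonic", "non_monotonic"),
        rank(-.data$strength, ties.method = "first"), NA_real_)) %>%
      dplyr::ungroup()
    gtab$top <- !is.na(gtab$rank_in_type) & gtab$rank_in_type <= top_k
    gtab
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("correlation_screen", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "top_k") <- top_k
  res
}

#' Export a screen's significant associations as a signed edge list
#'
#' One row per significant (group, pair): `var_a`, `var_b`, `sign`
#' (monotonic direction; 0 for non-monotonic), `weight` (strength) and
#' `group`, the content needed to draw a correlation network.
#'
#' @param screen A `correlation_screen` result.
#' @return A tibble.
#' @export
screen_edges <- function(screen) {
  sig <- screen[!is.na(screen$classification) &
                  screen$classification != "none", ]
  tibble::tibble(var_a = sig$var_a, var_b = sig$var_b,
                 sign = dplyr::coalesce(sig$sign, 0),
                 weight = sig$strength, group = sig$group,
                 classification = sig$classification)
}
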