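#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PERMANOVA fit
#'
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @return One-row tibble with term, df, pseudo-F, R2 and p.
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::tibble(term = x$grouping, strata = x$strata,
                 df_between = x$df[["between"]], df_within = x$df[["within"]],
                 pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value)
}

#' @rdname tidy.permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(term = x$grouping, strata = x$strata, R2 = x$R2,
                 p_value = x$p_value, pseudo_F = x$pseudo_F, n = x$n,
                 n_permutations = x$n_permutations, method = x$method)
}

#' Tidy an NMDS fit
#'
#' `tidy()` returns the sample coordinates; `glance()` the stress summary.
#'
#' @param x An `nmds_fit`.
#' @param ... Unused.
#' @export
tidy.nmds_fit <- function(x, ...) x$coordinates

#' @rdname tidy.nmds_fit
#' @export
glance.nmds_fit <- function(x, ...) {
  tibble::tibble(k = x$k, stress = x$stress, converged = x$converged,
                 n_restarts = x$n_restarts,
                 n_samples = nrow(x$coordinates))
}

#' Tidy an environmental surface fit
#'
#' @param x An `env_surface_fit`.
#' @param ... Unused.
#' @export
tidy.env_surface_fit <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, fitted = x$fitted)
}

#' @rdname tidy.env_surface_fit
#' @export
glance.env_surface_fit <- function(x, ...) {
  tibble::tibble(R2 = x$R2, n = length(x$fitted))
}

#' Tidy a stability fit
#'
#' `tidy()` returns the bootstrap slope draws; `glance()` the fitted curve
#' parameters and slope quantiles.
#'
#' @param x A `stability_fit`.
#' @param ... Unused.
#' @export
tidy.stability_fit <- function(x, ...) {
  tibble::tibble(group = x$group, replicate = seq_along(x$bootstrap_slopes),
                 slope = x$bootstrap_slopes)
}

#' @rdname tidy.stability_fit
#' @export
glance.stability_fit <- function(x, ...) {
  q <- quantile(x$bootstrap_slopes, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(group = x$group, a_hat = x$a_hat, b_hat = x$b_hat,
                 pairs_used = x$pairs_used, n_boot = x$n_boot,
                 slope_q025 = q[1], slope_median = q[2], slope_q975 = q[3])
}

#' Tidy a stability comparison
#'
#' `tidy()` stacks every group's bootstrap slopes; `glance()` gives one row
#' per group plus the overlap coefficients as attributes-free columns via
#' `x$overlap`.
#'
#' @param x A `stability_comparison`.
#' @param ... Unused.
#' @export
tidy.stability_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, tidy))
}

#' @rdname tidy.stability_comparison
#' @export
glance.stability_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, glance))
}
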