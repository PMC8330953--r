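#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_density geom_smooth labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot an NMDS ordination
#'
#' Scatter of the first two ordination axes, optionally coloured by a
#' metadata grouping.
#'
#' @param object An `nmds_fit`.
#' @param metadata Optional metadata joined on `sample_id`.
#' @param colour Optional metadata column name used for point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmds_fit <- function(object, metadata = NULL, colour = "texture",
                              ...) {
  df <- object$coordinates
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  p <- if (!is.null(metadata) && colour %in% names(df)) {
    ggplot(df, aes(.data$NMDS1, .data$NMDS2,
                   colour = .data[[colour]]))
  } else {
    ggplot(df, aes(.data$NMDS1, .data$NMDS2))
  }
  p + geom_point(alpha = 0.8) +
    labs(subtitle = sprintf("stress = %.3f", object$stress)) +
    theme_minimal()
}

#' Plot texture proportions over time
#'
#' Monthly texture proportions with their fitted linear trends.
#'
#' @param object A `texture_trends` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.texture_trends <- function(object, ...) {
  ggplot(object$proportions,
         aes(.data$month, .data$proportion, colour = .data$texture)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.6) +
    labs(x = "month", y = "proportion of samples") +
    theme_minimal()
}

#' Plot bootstrap slope distributions
#'
#' Kernel densities of the per-texture bootstrap slope distributions, the
#' comparison summarized by the overlap coefficient.
#'
#' @param object A `stability_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_comparison <- function(object, ...) {
  ggplot(tidy(object), aes(.data$slope, fill = .data$group,
                           colour = .data$group)) +
    geom_density(alpha = 0.3) +
    labs(x = "bootstrap slope b (per month)", y = "density") +
    theme_minimal()
}

#' Plot dissimilarity against time lag with the exponential fit
#'
#' @param pairs Output of [lag_pairs()].
#' @param fit Optional output of [fit_exponential()] for the same pairs.
#' @return A ggplot.
#' @export
plot_lag_decay <- function(pairs, fit = NULL) {
  p <- ggplot(pairs, aes(.data$lag, .data$dissimilarity)) +
    geom_point(alpha = 0.3) +
    labs(x = "time lag (months)", y = "Bray-Curtis dissimilarity") +
    theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(lag = seq(min(pairs$lag), max(pairs$lag),
                                     length.out = 100))
    grid$dissimilarity <- fit$a_hat * exp(fit$b_hat * grid$lag)
    p <- p + geom_line(data = grid, colour = "firebrick")
  }
  p
}
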