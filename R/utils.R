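#' @importFrom rlang %||% abort .data
#' @importFrom dplyr %>%
#' @importFrom stats setNames rnorm rbinom rmultinom rnbinom rgamma rt dt pt
#'   lm coef fitted resid model.matrix dist cmdscale isoreg density rexp
#'   runif var sd quantile median cor complete.cases predict
#' @importFrom utils head combn packageVersion
NULL

# wide counts tibble (id column + one column per sample) -> integer matrix
counts_to_matrix <- function(counts, id_col = NULL) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  if (is.null(id_col)) id_col <- names(counts)[1]
  m <- as.matrix(counts[, setdiff(names(counts), id_col), drop = FALSE])
  rownames(m) <- as.character(counts[[id_col]])
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m, id_col = "otu_id") {
  tibble::as_tibble(m, rownames = id_col)
}

check_counts <- function(m) {
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) abort("counts must be integers")
  if (anyDuplicated(rownames(m))) abort("duplicated OTU ids")
  if (anyDuplicated(colnames(m))) abort("duplicated sample ids")
  invisible(m)
}

# trapezoid rule on a uniform grid
trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

texture_levels <- function() c("no_foam", "crust", "foam")

texture_label <- function(x) {
  lab <- c(no_foam = "No-foam", crust = "Crust", foam = "Foam")
  unname(lab[as.character(x)])
}
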