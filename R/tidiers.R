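#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a benchmark report
#'
#' @param x A `pb_report`.
#' @param ... Unused.
#' @return The long-format rows tibble.
#' @export
tidy.pb_report <- function(x, ...) x$rows

#' One-row-per-group summary of a benchmark report
#'
#' @param x A `pb_report`.
#' @param which Name of the summary table to return (default: the first).
#' @param ... Unused.
#' @return A summary tibble.
#' @export
glance.pb_report <- function(x, which = NULL, ...) {
  if (is.null(which)) x$summary[[1]] else x$summary[[which]]
}

#' Tidy a moderated-t result
#'
#' @param x A [moderated_t()] result.
#' @param ... Unused.
#' @return Tibble with `gene`, `logfc`, `t`, `p_value`, `flat`.
#' @export
tidy.deg_result <- function(x, ...) {
  as_tibble(x)[, c("gene", "logfc", "t", "p_value", "flat")]
}

#' Hyperparameters of a moderated-t fit
#'
#' @param x A [moderated_t()] result.
#' @param ... Unused.
#' @return One-row tibble with `d0`, `s0sq`, `df_total`, `n_genes`.
#' @export
glance.deg_result <- function(x, ...) {
  tibble(d0 = attr(x, "d0"), s0sq = attr(x, "s0sq"),
         df_total = attr(x, "df_total"), n_genes = nrow(x))
}
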