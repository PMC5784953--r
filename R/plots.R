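#' Plot a benchmark report
#'
#' Dispatches on the experiment: sample-size reports draw the median DEP
#' proportion against the subsampling fraction per method; type-I-error
#' reports draw the per-method p-value histograms; single-gene reports draw
#' the pooled DEP-proportion curve against the induced shift.
#'
#' @param object A `pb_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pb_report <- function(object, ...) {
  s <- object$summary
  if (object$experiment == "ex1_sample_size") {
    ggplot2::ggplot(s$dep_by_fraction,
                    ggplot2::aes(x = .data$fraction,
                                 y = .data$median_dep_prop,
                                 colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "sample fraction",
                    y = "median proportion of DEPs (p < 0.05)")
  } else if (object$experiment == "ex2_type1") {
    ggplot2::ggplot(dplyr::filter(object$rows, .data$status == "ok"),
                    ggplot2::aes(x = .data$p_value)) +
      ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                              fill = "grey70", colour = "grey30") +
      ggplot2::facet_wrap(~method) +
      ggplot2::labs(x = "p-value under the null", y = "count")
  } else if (object$experiment %in% c("ex3_single_gene")) {
    ggplot2::ggplot(s$curve,
                    ggplot2::aes(x = .data$delta, y = .data$dep_prop,
                                 colour = .data$method)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "induced log2 fold change",
                    y = "proportion of DEPs across genes")
  } else {
    abort(paste0("no autoplot defined for ", object$experiment))
  }
}

#' Per-gene influence profile plot
#'
#' Bar chart of gene influences (proportion of DEP calls across all
#' replicates and increments) coloured by influence category.
#'
#' @param influence The `influence` summary tibble of [ex3_single_gene()].
#' @return A ggplot object.
#' @export
plot_influence <- function(influence) {
  ggplot2::ggplot(influence,
                  ggplot2::aes(x = .data$gene, y = .data$influence,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               drop = FALSE) +
    ggplot2::labs(y = "influence (proportion of DEPs)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
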