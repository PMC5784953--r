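#' Run a pathway analysis method over a pathway collection
#'
#' Applies the size/coverage filter, computes the gene-level moderated-t
#' statistics once (for the DEG-based methods), dispatches the requested
#' method on every retained pathway, and returns a tidy result table. With
#' `cfg$seed` set, the run is deterministic.
#'
#' @param name One of `"spia"`, `"prs"`, `"cepa"`, `"tappa"`,
#'   `"topologygsa"`, `"clipper"`, `"degraph"`.
#' @param data An [expression_dataset()].
#' @param pathways A list of [pathway_graph()] objects (or a single one).
#' @param cfg A [method_config()].
#' @param degs Optional precomputed [moderated_t()] result to reuse across
#'   methods.
#' @return A tibble with one row per retained pathway: `method`,
#'   `pathway_id`, `n_nodes`, `n_measured`, `n_deg`, `statistic`, `p_value`,
#'   `dep` (p < alpha), `status`, `extras` (list column), ordered by
#'   pathway id.
#' @export
run_method <- function(name, data, pathways, cfg = method_config(),
                       degs = NULL) {
  name <- match.arg(name, c("spia", "prs", "cepa", "tappa", "topologygsa",
                            "clipper", "degraph"))
  cfg <- as_method_config(cfg)
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  pathways <- filter_pathways(pathways, rownames(data$X))
  if (!length(pathways)) {
    return(empty_result_table())
  }
  with_seed(cfg$seed, {
    deg <- if (name %in% c("spia", "prs", "cepa")) {
      degs %||% moderated_t(data)
    } else NULL
    rows <- lapply(pathways, function(g) {
      switch(name,
        spia = spia(data, g, deg, cfg),
        prs = prs(data, g, deg, cfg),
        cepa = cepa_ora(data, g, deg, cfg),
        tappa = tappa(data, g, NULL, cfg),
        topologygsa = topology_gsa(data, g, cfg),
        clipper = clipper(data, g, cfg),
        degraph = degraph(data, g, cfg)
      )
    })
    out <- dplyr::bind_rows(rows)
    out$dep <- !is.na(out$p_value) & out$p_value < cfg$alpha
    out <- out[order(out$pathway_id),
               c("method", "pathway_id", "n_nodes", "n_measured", "n_deg",
                 "statistic", "p_value", "dep", "status", "extras")]
    attr(out, "config") <- cfg
    out
  })
}

empty_result_table <- function() {
  tibble(method = character(), pathway_id = character(),
         n_nodes = integer(), n_measured = integer(), n_deg = integer(),
         statistic = numeric(), p_value = numeric(), dep = logical(),
         status = character(), extras = list())
}

#' Run several methods on the same data and pathways
#'
#' Convenience wrapper over [run_method()]; the moderated-t statistics are
#' shared across the DEG-based methods and each method gets a seed derived
#' from `cfg$seed` so runs are reproducible but streams are independent.
#'
#' @param methods Character vector of method names.
#' @inheritParams run_method
#' @return Row-bound result tibble ordered by method, then pathway id.
#' @export
run_methods <- function(methods, data, pathways, cfg = method_config()) {
  cfg <- as_method_config(cfg)
  deg <- if (any(methods %in% c("spia", "prs", "cepa"))) {
    moderated_t(data)
  } else NULL
  out <- dplyr::bind_rows(lapply(seq_along(methods), function(i) {
    mcfg <- cfg
    if (!is.null(cfg$seed)) mcfg$seed <- (cfg$seed + 7919L * i) %% .Machine$integer.max
    run_method(methods[i], data, pathways, mcfg, degs = deg)
  }))
  out[order(out$method, out$pathway_id), ]
}
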