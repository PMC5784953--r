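#' Configuration shared by the pathway tests
#'
#' @param n_permutations Permutations / resampling draws for permutation
#'   p-values (default 1000).
#' @param alpha Pathway significance threshold for the DEP flag (default 0.05).
#' @param deg_theta Gene-level DEG threshold for the ORA methods (default 0.05).
#' @param seed Optional integer seed; when set, runs are reproducible.
#' @param degraph_k_fraction Fraction of the Laplacian eigenbasis retained by
#'   the graph-Fourier test: k = max(1, ceiling(fraction * component size)).
#'   `1` retains the full basis (classical Hotelling).
#' @param clipper_shrinkage Use James-Stein-type shrinkage covariance inside
#'   clique marginals (default TRUE). `clipper_lambda` overrides the
#'   estimated intensity (0 disables shrinkage exactly).
#' @param var_alpha Threshold on the variance-equality test that selects the
#'   pooled vs Behrens-Fisher branch of the two-step multivariable tests.
#' @param pert_p Tail convention for the perturbation bootstrap p-value:
#'   `"abs"` (default) compares net-accumulation magnitudes,
#'   `"median"` is two-sided around the null median.
#' @param clipper_lambda Optional fixed shrinkage intensity in `[0, 1]`.
#' @return A list of class `method_config`.
#' @export
method_config <- function(n_permutations = 1000, alpha = 0.05,
                          deg_theta = 0.05, seed = NULL,
                          degraph_k_fraction = 0.2,
                          clipper_shrinkage = TRUE, clipper_lambda = NULL,
                          var_alpha = 0.05, pert_p = c("abs", "median")) {
  structure(list(
    n_permutations = n_permutations, alpha = alpha, deg_theta = deg_theta,
    seed = seed, degraph_k_fraction = degraph_k_fraction,
    clipper_shrinkage = clipper_shrinkage, clipper_lambda = clipper_lambda,
    var_alpha = var_alpha, pert_p = match.arg(pert_p)
  ), class = "method_config")
}

as_method_config <- function(cfg) {
  if (inherits(cfg, "method_config")) cfg else do.call(method_config, cfg %||% list())
}

# One result row; `extras` is a named list serialized on export.
pathway_result <- function(pathway_id, method, statistic = NA_real_,
                           p_value = NA_real_, n_nodes = NA_integer_,
                           n_measured = NA_integer_, n_deg = NA_integer_,
                           status = "ok", extras = list()) {
  tibble(
    method = method, pathway_id = pathway_id,
    n_nodes = as.integer(n_nodes), n_measured = as.integer(n_measured),
    n_deg = as.integer(n_deg), statistic = statistic,
    p_value = if (status == "ok") p_value else NA_real_,
    status = status, extras = list(extras)
  )
}

# Per-node measurement / DE bookkeeping for the induced graph. A node is
# measured if any member gene is; its log fold change is the member value
# largest in magnitude; it is DE if any member gene is in `deg_set`.
node_stats <- function(g, deg, deg_set) {
  lfc <- setNames(deg$logfc, deg$gene)
  measured <- logical(nrow(g$nodes))
  nlfc <- rep(NA_real_, nrow(g$nodes))
  is_deg <- logical(nrow(g$nodes))
  for (i in seq_len(nrow(g$nodes))) {
    m <- intersect(g$nodes$members[[i]], deg$gene)
    if (!length(m)) next
    v <- lfc[m]
    measured[i] <- TRUE
    nlfc[i] <- v[which.max(abs(v))]
    is_deg[i] <- any(m %in% deg_set)
  }
  tibble(node_id = g$nodes$node_id, measured = measured, logfc = nlfc,
         is_deg = is_deg)
}
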