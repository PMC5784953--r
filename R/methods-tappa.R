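#' Pathway connectivity index test (TAPPA)
#'
#' Each sample's expression over the pathway is condensed into a Pathway
#' Connectivity Index: with per-gene z-scores \eqn{z_{is}} (standardized
#' across all samples) and the symmetrized adjacency with self-loops
#' \eqn{A^*},
#' \deqn{PCI_s = \frac{1}{|V|} \sum_{i \le j,\ A^*_{ij}=1}
#'       \mathrm{sign}(z_{is})\,\mathrm{sign}(z_{js})\sqrt{|z_{is}||z_{js}|}}
#' On an edgeless pathway only the self-loop terms survive and
#' \eqn{PCI_s = \sum_i |z_{is}| / |V|}. Groups are compared with a
#' two-sided Mann-Whitney test on the per-sample PCI values (exact when
#' both groups have at most 20 samples, tie-corrected normal approximation
#' otherwise). Genes constant across samples are dropped with a warning.
#'
#' @inheritParams spia
#' @return A one-row pathway result tibble; the statistic is the rank-sum
#'   statistic, mean PCI difference (group 2 minus group 1) in `extras`.
#' @export
tappa <- function(data, graph, degs = NULL, cfg = method_config()) {
  cfg <- as_method_config(cfg)
  g <- induce_measured(graph, rownames(data$X))
  pg <- intersect(pathway_genes(g), rownames(data$X))
  base <- function(...) pathway_result(graph$pathway_id, "tappa",
                                       n_nodes = nrow(graph$nodes),
                                       n_measured = length(pg),
                                       n_deg = NA_integer_, ...)
  if (length(pg) < 2 || data$n1 < 2 || data$n2 < 2) {
    return(base(status = "not_testable"))
  }
  pci <- tappa_pci(data, g)
  if (is.null(pci)) return(base(status = "degenerate"))

  exact <- data$n1 <= 20 && data$n2 <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(pci[data$y == 2L], pci[data$y == 1L],
                       exact = exact, correct = TRUE)
  )
  base(statistic = unname(wt$statistic), p_value = wt$p.value,
       extras = list(pci_diff = mean(pci[data$y == 2L]) -
                       mean(pci[data$y == 1L])))
}

#' Per-sample pathway connectivity index
#'
#' The PCI score underlying [tappa()] (see there for the formula). Genes
#' are standardized across all samples; combined nodes use the mean of
#' their member genes' profiles; constant nodes are dropped with a warning.
#'
#' @param data An [expression_dataset()].
#' @param graph A [pathway_graph()] (restricted to measured genes
#'   internally).
#' @return Numeric vector of per-sample PCI values, or `NULL` when fewer
#'   than two non-constant nodes remain.
#' @export
tappa_pci <- function(data, graph) {
  g <- induce_measured(graph, rownames(data$X))
  prof <- t(vapply(g$nodes$members, function(m) {
    m <- intersect(m, rownames(data$X))
    colMeans(data$X[m, , drop = FALSE])
  }, numeric(ncol(data$X))))
  rownames(prof) <- g$nodes$node_id
  sds <- apply(prof, 1, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0), " constant node(s) in pathway ",
                g$pathway_id))
    prof <- prof[sds > 0, , drop = FALSE]
    if (nrow(prof) < 2) return(NULL)
  }
  z <- (prof - rowMeans(prof)) / apply(prof, 1, sd)
  f <- sign(z) * sqrt(abs(z))

  ids <- rownames(prof)
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- g$edges[g$edges$source %in% ids & g$edges$target %in% ids, ,
               drop = FALSE]
  if (nrow(e)) {
    A[cbind(e$source, e$target)] <- 1
    A[cbind(e$target, e$source)] <- 1
  }
  diag(A) <- 1
  # sum over unordered pairs incl. diagonal = (quadratic form + diag)/2
  q <- colSums(f * (A %*% f))
  setNames((q + colSums(f^2)) / 2 / length(ids), colnames(data$X))
}
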