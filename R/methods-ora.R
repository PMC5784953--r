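# The three DEG-list (ORA) pathway tests with competitive, gene-permutation
# nulls: signed perturbation propagation (SPIA), downstream-DEG weighting
# (PRS) and centrality weighting (CePa).

# Gene-level universe bookkeeping shared by the competitive nulls.
ora_context <- function(data, deg, deg_theta) {
  deg_set <- call_degs(deg, deg_theta)
  list(
    universe = deg$gene,
    n_univ = nrow(deg),
    deg_set = deg_set,
    deg_lfc = deg$logfc[match(deg_set, deg$gene)]
  )
}

# Random DEG-status draws over the measured universe, aggregated to nodes of
# `g`: `ind` marks nodes containing at least one drawn gene; `val` carries
# the drawn gene's assigned log fold change (largest in magnitude per node).
draw_null_deg <- function(g, ctx, n_draws, with_values = FALSE) {
  nodes <- g$nodes$node_id
  members <- g$nodes$members
  single <- all(lengths(members) == 1L)
  n_deg <- length(ctx$deg_set)
  ind <- matrix(FALSE, length(nodes), n_draws)
  val <- if (with_values) matrix(0, length(nodes), n_draws) else NULL
  if (n_deg == 0) return(list(ind = ind, val = val))
  gene_ids <- if (single) unlist(members, use.names = FALSE) else NULL
  for (b in seq_len(n_draws)) {
    hit <- sample(ctx$universe, n_deg)
    vals <- if (with_values) sample(ctx$deg_lfc) else NULL
    if (single) {
      m <- match(gene_ids, hit)
      ind[, b] <- !is.na(m)
      if (with_values) val[!is.na(m), b] <- vals[m[!is.na(m)]]
    } else {
      for (i in seq_along(members)) {
        m <- match(members[[i]], hit)
        m <- m[!is.na(m)]
        if (length(m)) {
          ind[i, b] <- TRUE
          if (with_values) val[i, b] <- vals[m][which.max(abs(vals[m]))]
        }
      }
    }
  }
  list(ind = ind, val = val)
}

pathway_deg_counts <- function(g, ctx) {
  pg <- intersect(pathway_genes(g), ctx$universe)
  list(n_measured = length(pg), n_deg = sum(pg %in% ctx$deg_set), genes = pg)
}

#' Signed perturbation propagation test (SPIA)
#'
#' Log fold changes of the pathway's differentially expressed genes are
#' propagated through the signed interaction network: with B the
#' normalized signed adjacency (`B[i, j] = sign(j -> i) / N_ds(j)`, where
#' `N_ds(j)` counts j's outgoing signed interactions), the perturbation
#' factors solve `(I - B) PF = dE` and the net accumulation is
#' `Acc = PF - dE`, summed into the pathway statistic `tA`. Significance
#' combines a hypergeometric over-representation p-value (`pNDE`) with a
#' gene-permutation bootstrap p-value for `tA` (`pPERT`, observed DEG log
#' fold changes placed on random pathway nodes) via `pG = c - c log c`,
#' `c = pNDE * pPERT`. With no DEGs in the pathway, or no signed
#' interactions to propagate over, `pG` reduces to `pNDE`.
#'
#' @param data An [expression_dataset()].
#' @param graph A [pathway_graph()].
#' @param degs A [moderated_t()] result for `data` (computed when `NULL`).
#' @param cfg A [method_config()].
#' @return A one-row pathway result tibble.
#' @export
spia <- function(data, graph, degs = NULL, cfg = method_config()) {
  cfg <- as_method_config(cfg)
  deg <- degs %||% moderated_t(data)
  ctx <- ora_context(data, deg, cfg$deg_theta)
  g <- induce_measured(graph, ctx$universe)
  cnt <- pathway_deg_counts(g, ctx)
  base <- function(...) pathway_result(graph$pathway_id, "spia",
                                       n_nodes = nrow(graph$nodes),
                                       n_measured = cnt$n_measured,
                                       n_deg = cnt$n_deg, ...)
  if (cnt$n_measured < 1) return(base(status = "not_testable"))

  ns <- node_stats(g, deg, ctx$deg_set)
  B <- signed_adjacency(g)
  dE <- ifelse(ns$is_deg, ns$logfc, 0)
  dE[is.na(dE)] <- 0
  IB <- diag(nrow(B)) - B
  M <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(M)) return(base(status = "degenerate"))
  w <- colSums(M) - 1 # tA = sum(Acc) = sum_j w_j * dE_j
  tA <- sum(w * dE)

  m_deg <- length(ctx$deg_set)
  pnde <- if (m_deg == 0) 1 else {
    phyper(cnt$n_deg - 1, m_deg, ctx$n_univ - m_deg, cnt$n_measured,
           lower.tail = FALSE)
  }

  n_deg_nodes <- sum(ns$is_deg)
  propagates <- any(abs(w) > 1e-12)
  if (n_deg_nodes == 0 || !propagates || m_deg == 0) {
    pg <- pnde
    ppert <- NA_real_
  } else {
    N <- cfg$n_permutations
    nn <- nrow(ns)
    t_null <- with_seed(cfg$seed, vapply(seq_len(N), function(b) {
      pos <- sample.int(nn, min(n_deg_nodes, nn))
      vals <- sample(ctx$deg_lfc, length(pos), replace = m_deg < length(pos))
      sum(w[pos] * vals)
    }, numeric(1)))
    ppert <- if (cfg$pert_p == "abs") {
      (1 + sum(abs(t_null) >= abs(tA))) / (1 + N)
    } else {
      md <- median(t_null)
      (1 + sum(abs(t_null - md) >= abs(tA - md))) / (1 + N)
    }
    cc <- pnde * ppert
    pg <- if (cc <= 0) 0 else if (cc >= 1) 1 else cc - cc * log(cc)
  }
  base(statistic = tA, p_value = pg,
       extras = list(pNDE = pnde, pPERT = ppert, tA = tA))
}

#' Propagate a perturbation through a pathway's signed network
#'
#' The linear propagation at the core of the impact-factor test: solves
#' `(I - B) PF = dE` for the perturbation factors, where B is the
#' normalized signed adjacency of the graph, and returns the accumulations
#' `Acc = PF - dE` and their sum `tA`.
#'
#' @param graph A [pathway_graph()].
#' @param delta_e Named numeric vector of initial perturbations (log fold
#'   changes on the DE nodes, 0 elsewhere); names must match node ids.
#'   Unnamed vectors are taken in node order.
#' @return List with `pf`, `acc` (named numeric) and `ta` (scalar), or
#'   `NULL` when `I - B` is singular.
#' @export
spia_propagation <- function(graph, delta_e) {
  B <- signed_adjacency(graph)
  ids <- rownames(B)
  dE <- numeric(length(ids))
  names(dE) <- ids
  if (is.null(names(delta_e))) {
    dE[] <- delta_e
  } else {
    dE[names(delta_e)] <- delta_e
  }
  pf <- tryCatch(solve(diag(length(ids)) - B, dE), error = function(e) NULL)
  if (is.null(pf)) return(NULL)
  acc <- pf - dE
  list(pf = setNames(as.numeric(pf), ids), acc = setNames(as.numeric(acc), ids),
       ta = sum(acc))
}

# Normalized signed adjacency: column j distributes j's signal equally over
# its signed out-edges; neutral (sign 0) interactions carry nothing.
signed_adjacency <- function(g) {
  ids <- g$nodes$node_id
  n <- length(ids)
  B <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- g$edges[g$edges$sign != 0L, , drop = FALSE]
  if (!nrow(e)) return(B)
  und <- e[!e$directed, , drop = FALSE]
  if (nrow(und)) {
    rev <- und; rev$source <- und$target; rev$target <- und$source
    e <- dplyr::bind_rows(e, rev)
  }
  for (i in seq_len(nrow(e))) {
    B[e$target[i], e$source[i]] <- B[e$target[i], e$source[i]] + e$sign[i]
  }
  nds <- vapply(ids, function(j) sum(e$source == j), numeric(1))
  for (j in seq_len(n)) if (nds[j] > 0) B[, j] <- B[, j] / nds[j]
  B
}

#' Downstream-DEG weighted pathway score (PRS)
#'
#' Each differentially expressed pathway node contributes its absolute log
#' fold change weighted by `1 +` the number of distinct differentially
#' expressed nodes reachable from it along directed interactions. The
#' pathway score is the sum over DE nodes; significance comes from
#' permuting DEG statuses (with their log fold changes) over all measured
#' genes. The score normalized by the null mean is reported in `extras`.
#'
#' @inheritParams spia
#' @return A one-row pathway result tibble.
#' @export
prs <- function(data, graph, degs = NULL, cfg = method_config()) {
  cfg <- as_method_config(cfg)
  deg <- degs %||% moderated_t(data)
  ctx <- ora_context(data, deg, cfg$deg_theta)
  g <- induce_measured(graph, ctx$universe)
  cnt <- pathway_deg_counts(g, ctx)
  base <- function(...) pathway_result(graph$pathway_id, "prs",
                                       n_nodes = nrow(graph$nodes),
                                       n_measured = cnt$n_measured,
                                       n_deg = cnt$n_deg, ...)
  if (cnt$n_measured < 1) return(base(status = "not_testable"))
  if (length(ctx$deg_set) == 0) return(base(status = "not_testable"))

  ns <- node_stats(g, deg, ctx$deg_set)
  R <- reach_matrix(g) # R[v, u] = 1 iff u reachable from v, u != v
  score_of <- function(ind, val) {
    w <- 1 + as.vector(R %*% ind)
    sum(ind * abs(val) * w)
  }
  obs_val <- ifelse(is.na(ns$logfc), 0, ns$logfc)
  observed <- score_of(as.numeric(ns$is_deg), obs_val)

  N <- cfg$n_permutations
  nulls <- with_seed(cfg$seed, draw_null_deg(g, ctx, N, with_values = TRUE))
  Wn <- 1 + R %*% nulls$ind
  null_scores <- colSums(nulls$ind * abs(nulls$val) * Wn)
  p <- perm_pvalue(null_scores, observed)
  nm <- mean(null_scores)
  base(statistic = observed, p_value = p,
       extras = list(normalized_score = if (nm > 0) observed / nm else NA_real_,
                     null_mean = nm))
}

reach_matrix <- function(g) {
  ig <- pathway_igraph(g, "directed")
  d <- igraph::distances(ig, mode = "out")
  m <- is.finite(d) & d > 0
  storage.mode(m) <- "numeric"
  m[g$nodes$node_id, g$nodes$node_id, drop = FALSE]
}

#' Centrality-weighted over-representation test (CePa, ORA form)
#'
#' The pathway's differentially expressed nodes are summed under six node
#' weighting schemes (in/out degree, betweenness, in/out reach, equal
#' weight). For each scheme, a competitive null draws the same number of
#' DEGs uniformly from the measured universe and recomputes the score; the
#' overall pathway p-value is the minimum of the six permutation p-values,
#' deliberately without multiplicity correction — the anti-conservative
#' behaviour this induces is itself one of the benchmarked findings.
#'
#' @inheritParams spia
#' @return A one-row pathway result tibble; per-centrality p-values are in
#'   `extras`.
#' @export
cepa_ora <- function(data, graph, degs = NULL, cfg = method_config()) {
  cfg <- as_method_config(cfg)
  deg <- degs %||% moderated_t(data)
  ctx <- ora_context(data, deg, cfg$deg_theta)
  g <- induce_measured(graph, ctx$universe)
  cnt <- pathway_deg_counts(g, ctx)
  base <- function(...) pathway_result(graph$pathway_id, "cepa",
                                       n_nodes = nrow(graph$nodes),
                                       n_measured = cnt$n_measured,
                                       n_deg = cnt$n_deg, ...)
  if (cnt$n_measured < 1) return(base(status = "not_testable"))
  if (length(ctx$deg_set) == 0) return(base(status = "not_testable"))

  ns <- node_stats(g, deg, ctx$deg_set)
  cent <- node_centralities(g)
  cent <- cent[match(ns$node_id, cent$node_id), ]
  W <- as.matrix(cent[, c("in_degree", "out_degree", "betweenness",
                          "in_reach", "out_reach", "equal_weight")])
  observed <- as.vector(t(W) %*% as.numeric(ns$is_deg))

  N <- cfg$n_permutations
  nulls <- with_seed(cfg$seed, draw_null_deg(g, ctx, N))
  storage.mode(nulls$ind) <- "numeric"
  null_scores <- t(W) %*% nulls$ind # 6 x N
  pc <- vapply(seq_len(6), function(i) perm_pvalue(null_scores[i, ], observed[i]),
               numeric(1))
  names(pc) <- colnames(W)
  i_min <- which.min(pc)
  base(statistic = observed[i_min], p_value = min(pc),
       extras = list(centrality_p = as.list(pc),
                     best_centrality = colnames(W)[i_min]))
}
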