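#' Node centralities of a pathway graph
#'
#' The six node-weighting schemes used by the centrality-weighted
#' over-representation method: in/out degree, shortest-path betweenness on
#' the directed graph, in/out reach (the largest finite shortest-path
#' distance into / out of a node) and a constant equal weight of 1.
#' Undirected edges count once in each direction.
#'
#' @param g A [pathway_graph()].
#' @return A tibble with one row per node: `node_id`, `in_degree`,
#'   `out_degree`, `betweenness`, `in_reach`, `out_reach`, `equal_weight`.
#' @export
node_centralities <- function(g) {
  ig <- pathway_igraph(g, "directed")
  n <- igraph::vcount(ig)
  dmat <- igraph::distances(ig, mode = "out") # rows: from, cols: to
  reach_stat <- function(d) {
    d[is.infinite(d)] <- NA
    diag(d) <- NA
    apply(d, 2, function(col) {
      m <- suppressWarnings(max(col, na.rm = TRUE))
      if (is.finite(m)) m else 0
    })
  }
  tibble(
    node_id = igraph::V(ig)$name,
    in_degree = as.integer(igraph::degree(ig, mode = "in")),
    out_degree = as.integer(igraph::degree(ig, mode = "out")),
    betweenness = unname(igraph::betweenness(ig, directed = TRUE)),
    in_reach = unname(reach_stat(dmat)),      # longest finite path into v
    out_reach = unname(reach_stat(t(dmat))),  # symmetric, out of v
    equal_weight = rep(1, n)
  )
}

#' Weakly connected components over measured genes
#'
#' Induces the subgraph on the measured genes and returns its weakly
#' connected components (with their induced edges), sorted by decreasing
#' size and then by lexicographic first gene.
#'
#' @param g A [pathway_graph()].
#' @param measured_genes Character vector.
#' @return List of [pathway_graph()] objects, one per component.
#' @export
measured_components <- function(g, measured_genes) {
  sub <- induce_measured(g, measured_genes)
  if (nrow(sub$nodes) == 0) return(list())
  ig <- pathway_igraph(sub, "undirected")
  comp <- igraph::components(ig, mode = "weak")
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  unname(lapply(groups[ord], function(ids) induce_nodes(sub, ids)))
}

# ---- decomposable model support ------------------------------------------

# Break directed cycles deterministically: while a directed cycle exists,
# remove the lexicographically-last directed edge on it. Undirected edges
# never form directed cycles here because moralization symmetrises them.
break_cycles <- function(edges) {
  removed <- character()
  repeat {
    dir_e <- edges[edges$directed, , drop = FALSE]
    if (!nrow(dir_e)) break
    ig <- igraph::graph_from_data_frame(dir_e[, c("source", "target")],
                                        directed = TRUE)
    if (igraph::is_dag(ig)) break
    cyc <- find_cycle(ig)
    cyc_edges <- paste(cyc$from, cyc$to)
    drop_key <- max(cyc_edges)
    hit <- which(edges$directed &
                   paste(edges$source, edges$target) == drop_key)[1]
    removed <- c(removed, drop_key)
    edges <- edges[-hit, , drop = FALSE]
  }
  attr(edges, "removed_edges") <- removed
  edges
}

# One directed cycle of a non-DAG, as a data frame of its arcs.
find_cycle <- function(ig) {
  scc <- igraph::components(ig, mode = "strong")
  big <- which(scc$csize > 1)[1]
  verts <- names(scc$membership)[scc$membership == big]
  sub <- igraph::induced_subgraph(ig, verts)
  start <- igraph::V(sub)$name[1]
  # walk successors inside the SCC until the start vertex recurs
  path <- start
  cur <- start
  repeat {
    nxt <- sort(names(igraph::neighbors(sub, cur, mode = "out")))[1]
    if (nxt %in% path) {
      cyc <- c(path[which(path == nxt):length(path)], nxt)
      return(data.frame(from = cyc[-length(cyc)], to = cyc[-1]))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

#' Moralize and triangulate a pathway graph into a clique tree
#'
#' Restricts the graph to measured genes, breaks any directed cycles
#' (removing the lexicographically-last edge of each cycle), moralizes the
#' resulting DAG (marries co-parents, drops directions, keeps undirected
#' edges), triangulates with deterministic minimum-fill (lexicographic
#' tie-break), and emits the cliques and separators of a junction tree in a
#' running-intersection order obtained by maximum-cardinality search. This
#' decomposition is what the Gaussian-graphical-model tests estimate their
#' constrained covariances on.
#'
#' @param g A [pathway_graph()].
#' @param measured_genes Character vector; defaults to all genes.
#' @return A list of class `clique_decomposition`: `nodes`, `adjacency`
#'   (chordal, logical matrix), `cliques` (list of character vectors in RIP
#'   order), `separators` (parallel list; first is empty), `max_clique_size`,
#'   `removed_edges`.
#' @export
decompose_to_cliques <- function(g, measured_genes = pathway_genes(g)) {
  sub <- induce_measured(g, measured_genes)
  ids <- sort(sub$nodes$node_id)
  n <- length(ids)
  edges <- break_cycles(sub$edges)
  removed <- attr(edges, "removed_edges")

  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    add_und <- function(a, b) {
      adj[cbind(a, b)] <<- TRUE
      adj[cbind(b, a)] <<- TRUE
    }
    add_und(edges$source, edges$target)
    # marry parents: for each child, connect every pair of its parents
    dir_e <- edges[edges$directed, , drop = FALSE]
    for (child in unique(dir_e$target)) {
      par <- unique(dir_e$source[dir_e$target == child])
      if (length(par) > 1) {
        prs <- t(combn(sort(par), 2))
        add_und(prs[, 1], prs[, 2])
      }
    }
  }
  diag(adj) <- FALSE

  adj <- min_fill_triangulate(adj)
  cd <- chordal_cliques(adj)
  structure(
    list(nodes = ids, adjacency = adj, cliques = cd$cliques,
         separators = cd$separators,
         max_clique_size = if (length(cd$cliques)) max(lengths(cd$cliques)) else 0L,
         removed_edges = removed),
    class = "clique_decomposition"
  )
}

# Deterministic min-fill triangulation: repeatedly eliminate the vertex
# whose neighbourhood needs the fewest fill edges (lexicographic tie-break),
# adding those fill edges to the running graph.
min_fill_triangulate <- function(adj) {
  ids <- rownames(adj)
  work <- adj
  alive <- ids
  while (length(alive) > 1) {
    fill_count <- vapply(alive, function(v) {
      nb <- alive[work[v, alive]]
      if (length(nb) < 2) return(0L)
      prs <- combn(nb, 2)
      sum(!work[cbind(prs[1, ], prs[2, ])])
    }, integer(1))
    v <- alive[order(fill_count, alive)][1]
    nb <- alive[work[v, alive]]
    if (length(nb) > 1) {
      prs <- combn(nb, 2)
      miss <- !work[cbind(prs[1, ], prs[2, ])]
      if (any(miss)) {
        a <- prs[1, miss]; b <- prs[2, miss]
        work[cbind(a, b)] <- TRUE; work[cbind(b, a)] <- TRUE
        adj[cbind(a, b)] <- TRUE; adj[cbind(b, a)] <- TRUE
      }
    }
    alive <- setdiff(alive, v)
  }
  adj
}

# Maximum-cardinality search on a chordal graph: perfect numbering, maximal
# cliques, and separators in running-intersection order.
chordal_cliques <- function(adj) {
  ids <- rownames(adj)
  n <- length(ids)
  if (n == 0) return(list(cliques = list(), separators = list()))
  numbered <- character()
  weight <- setNames(rep(0L, n), ids)
  order_mcs <- character(n)
  for (i in seq_len(n)) {
    cand <- setdiff(ids, numbered)
    v <- cand[order(-weight[cand], cand)][1]
    order_mcs[i] <- v
    numbered <- c(numbered, v)
    nb <- ids[adj[v, ]]
    bump <- setdiff(nb, numbered)
    weight[bump] <- weight[bump] + 1L
  }
  rank <- setNames(seq_len(n), order_mcs)
  # candidate cliques: v plus its earlier neighbours, for each v
  cands <- lapply(seq_len(n), function(i) {
    v <- order_mcs[i]
    nb <- ids[adj[v, ]]
    sort(c(v, nb[rank[nb] < i]))
  })
  # keep maximal ones (a candidate is non-maximal iff the next vertex's
  # earlier-neighbourhood contains it entirely); simple subset filter
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keep[i] &&
          length(cands[[i]]) < length(cands[[j]]) &&
          all(cands[[i]] %in% cands[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cliques <- unique(cands[keep])
  # RIP order: by the highest MCS rank occurring in the clique
  hi <- vapply(cliques, function(cl) max(rank[cl]), numeric(1))
  cliques <- cliques[order(hi)]
  seps <- vector("list", length(cliques))
  seen <- character()
  for (k in seq_along(cliques)) {
    seps[[k]] <- sort(intersect(cliques[[k]], seen))
    seen <- union(seen, cliques[[k]])
  }
  list(cliques = cliques, separators = seps)
}

# ---- motif enumeration ----------------------------------------------------

#' Enumerate connected topological motifs
#'
#' All gene subsets of size `k` whose induced directed subgraph is weakly
#' connected, grouped into digraph-isomorphism classes (interaction types
#' and signs are ignored; undirected edges act as arc pairs). Enumeration
#' uses the ESU connected-subgraph algorithm, so it scales to pathway-sized
#' graphs without scanning all subsets.
#'
#' @param g A [pathway_graph()].
#' @param k Motif size, 3, 4 or 5.
#' @return A tibble with columns `genes` (list of sorted gene id vectors),
#'   `iso_class` (canonical digraph code shared by isomorphic instances) and
#'   `size`.
#' @export
enumerate_motifs <- function(g, k) {
  stopifnot(k %in% 3:5, nrow(g$nodes) >= k)
  ig_dir <- pathway_igraph(g, "directed")
  ig_und <- pathway_igraph(g, "undirected")
  ids <- igraph::V(ig_und)$name
  nb <- lapply(ids, function(v) match(names(igraph::neighbors(ig_und, v)), ids))
  names(nb) <- ids

  subsets <- list()
  # ESU: extend from each root using only higher-indexed vertices
  extend <- function(sub, extension, root) {
    if (length(sub) == k) {
      subsets[[length(subsets) + 1L]] <<- sub
      return()
    }
    while (length(extension)) {
      w <- extension[1]
      extension <- extension[-1]
      excl <- unique(unlist(nb[sub]))
      new_ext <- setdiff(nb[[w]], c(sub, w, excl))
      new_ext <- new_ext[new_ext > root]
      extend(c(sub, w), unique(c(extension, new_ext)), root)
    }
  }
  for (v in seq_along(ids)) {
    ext <- nb[[v]][nb[[v]] > v]
    extend(v, ext, v)
  }
  if (!length(subsets)) {
    return(tibble(genes = list(), iso_class = character(), size = integer()))
  }
  genes <- lapply(subsets, function(s) sort(ids[s]))
  iso <- vapply(genes, function(gs) {
    canonical_digraph_code(igraph::induced_subgraph(ig_dir, gs))
  }, character(1))
  tibble(genes = genes, iso_class = iso, size = as.integer(k))
}

# Canonical string code of a digraph under vertex relabelling (BLISS).
canonical_digraph_code <- function(ig) {
  ig <- igraph::simplify(ig)
  perm <- igraph::canonical_permutation(ig)$labeling
  cg <- igraph::permute(ig, perm)
  el <- igraph::as_edgelist(cg, names = FALSE)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("n", igraph::vcount(cg), ":",
         paste(el[, 1], el[, 2], sep = ">", collapse = ","))
}
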