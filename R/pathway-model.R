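#' Interaction sign vocabulary
#'
#' Controlled vocabulary of interaction types and the sign each one carries
#' when a pathway is converted into a signed gene network. Activating
#' chemistry (activation, expression, phosphorylation) maps to +1, inhibitory
#' chemistry (inhibition, repression, dephosphorylation) to -1, and
#' relationships that move no signal of their own (binding, association,
#' indirect effects, compound-bridged links) are neutral (0).
#'
#' @return A tibble with columns `interaction_type` and `sign`.
#' @export
interaction_signs <- function() {
  tibble(
    interaction_type = c(
      "activation", "expression", "phosphorylation",
      "inhibition", "repression", "dephosphorylation",
      "binding", "association", "indirect", "compound", "neutral"
    ),
    sign = c(1L, 1L, 1L, -1L, -1L, -1L, 0L, 0L, 0L, 0L, 0L)
  )
}

interaction_sign <- function(type) {
  tab <- interaction_signs()
  idx <- match(type, tab$interaction_type)
  if (anyNA(idx)) {
    bad <- unique(type[is.na(idx)])
    abort(paste0("unknown interaction_type: ", paste(bad, collapse = ", ")))
  }
  tab$sign[idx]
}

#' Construct a raw (un-preprocessed) pathway
#'
#' A raw pathway keeps the database-level node structure: plain gene nodes,
#' multi-subunit `complex` nodes, `family` nodes (interchangeable members) and
#' non-gene `compound` nodes (metabolites), plus typed, optionally directed
#' edges between them. [preprocess_topology()] turns this into a gene-level
#' [pathway_graph()].
#'
#' @param pathway_id Single string identifying the pathway.
#' @param nodes Data frame with columns `node_id`, `kind` (one of `gene`,
#'   `complex`, `family`, `compound`) and `members` (list column of gene id
#'   character vectors; empty for `gene` and `compound` nodes).
#' @param edges Data frame with columns `source`, `target`, `directed`
#'   (logical) and `interaction_type` (see [interaction_signs()]).
#' @return An object of class `raw_pathway`.
#' @export
raw_pathway <- function(pathway_id, nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!all(c("node_id", "kind", "members") %in% names(nodes))) {
    abort("nodes must have columns node_id, kind, members")
  }
  if (anyDuplicated(nodes$node_id)) {
    abort(paste0("duplicated node ids in pathway ", pathway_id))
  }
  if (!all(nodes$kind %in% c("gene", "complex", "family", "compound"))) {
    abort("node kind must be one of gene, complex, family, compound")
  }
  n_mem <- lengths(nodes$members)
  if (any(nodes$kind %in% c("complex", "family") & n_mem < 2)) {
    abort("complex/family nodes must list at least 2 members")
  }
  if (any(nodes$kind == "compound" & n_mem != 0)) {
    abort("compound nodes carry no gene members")
  }
  if (nrow(edges)) {
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$node_id)
    if (length(missing_ep)) {
      abort(paste0("edge endpoint not declared as node: ",
                   paste(missing_ep, collapse = ", ")))
    }
    interaction_sign(edges$interaction_type) # validates the vocabulary
  }
  structure(
    list(pathway_id = pathway_id, nodes = nodes, edges = edges),
    class = "raw_pathway"
  )
}

#' Construct a gene-level pathway graph
#'
#' The working representation used by all analysis methods: a signed, typed
#' interaction network G = (V, E) whose nodes are genes (or, under the
#' combined-node pre-processing convention, nodes carrying several member
#' genes). `provenance` records which pre-processing produced the graph:
#' `"GPT"` for the expanded convention, `"MSPT"` for a method-specific
#' convention, `"NOGPT"` for the edgeless gene-set view.
#'
#' @param pathway_id Single string.
#' @param nodes Tibble with columns `node_id` and `members` (list column;
#'   for plain gene nodes `members` is the node id itself).
#' @param edges Tibble with columns `source`, `target`, `directed`,
#'   `interaction_type`, `sign`.
#' @param provenance One of `"GPT"`, `"MSPT"`, `"NOGPT"`.
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, nodes, edges, provenance = "GPT") {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(provenance %in% c("GPT", "MSPT", "NOGPT"))
  if (provenance == "NOGPT" && nrow(edges) > 0) {
    abort("NOGPT graphs must be edgeless")
  }
  if (nrow(edges)) {
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$node_id)
    if (length(missing_ep)) {
      abort(paste0("edge endpoint not in node set: ",
                   paste(missing_ep, collapse = ", ")))
    }
  }
  structure(
    list(pathway_id = pathway_id,
         nodes = nodes[order(nodes$node_id), , drop = FALSE],
         edges = edges,
         provenance = provenance),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s [%s]: %d nodes (%d genes), %d edges\n",
              x$pathway_id, x$provenance, nrow(x$nodes),
              length(pathway_genes(x)), nrow(x$edges)))
  invisible(x)
}

#' @export
print.raw_pathway <- function(x, ...) {
  cat(sprintf("<raw_pathway> %s: %d nodes, %d edges\n",
              x$pathway_id, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Genes of a pathway graph
#'
#' All gene ids covered by the graph's nodes (union of node members).
#'
#' @param g A [pathway_graph()].
#' @return Sorted character vector of gene ids.
#' @export
pathway_genes <- function(g) {
  sort(unique(unlist(g$nodes$members, use.names = FALSE)))
}

gene_nodes <- function(ids) {
  tibble(node_id = ids, members = as.list(ids))
}

# igraph view of a pathway graph. Undirected edges are stored once and
# expanded to a pair of opposite arcs whenever a directed algorithm needs
# them (mode = "directed"); mode = "undirected" drops directions entirely.
pathway_igraph <- function(g, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  e <- g$edges
  if (mode == "directed") {
    if (nrow(e)) {
      und <- e[!e$directed, , drop = FALSE]
      if (nrow(und)) {
        rev <- und
        rev$source <- und$target
        rev$target <- und$source
        e <- dplyr::bind_rows(e, rev)
      }
      e <- dplyr::distinct(e, .data$source, .data$target, .data$sign,
                           .keep_all = TRUE)
    }
    ig <- igraph::graph_from_data_frame(
      e[, c("source", "target", "sign")],
      directed = TRUE,
      vertices = data.frame(name = g$nodes$node_id)
    )
  } else {
    ig <- igraph::graph_from_data_frame(
      e[, c("source", "target")],
      directed = FALSE,
      vertices = data.frame(name = g$nodes$node_id)
    )
    ig <- igraph::simplify(ig)
  }
  ig
}

induce_nodes <- function(g, keep_nodes, provenance = g$provenance) {
  keep <- g$nodes$node_id %in% keep_nodes
  nodes <- g$nodes[keep, , drop = FALSE]
  e <- g$edges
  e <- e[e$source %in% nodes$node_id & e$target %in% nodes$node_id, ,
         drop = FALSE]
  pathway_graph(g$pathway_id, nodes, e, provenance)
}

# Restrict a pathway graph to nodes with at least one measured member gene.
# All methods operate on this induced subgraph; edges through unmeasured
# nodes are not contracted.
induce_measured <- function(g, measured_genes) {
  keep <- vapply(g$nodes$members, function(m) any(m %in% measured_genes),
                 logical(1))
  induce_nodes(g, g$nodes$node_id[keep])
}
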