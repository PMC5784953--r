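#' Pre-process a raw pathway into a gene-level graph
#'
#' Converts database-level pathway structure (complexes, gene families,
#' compound nodes) into a signed gene network under one of the conventions
#' whose downstream consequences the benchmark experiments probe:
#'
#' * `"gpt"` — expanded convention: complexes are replaced by their member
#'   genes joined pairwise by undirected neutral (binding) edges, family
#'   members each inherit all edges of the family node, and compound nodes
#'   are removed with their incident interactions bridged (`A -> compound ->
#'   B` becomes `A -> B`).
#' * `"mspt_combined"` — PRS/CePa-style original convention: complexes and
#'   families are kept as single combined nodes carrying all member gene
#'   ids; compounds are bridged as under `"gpt"`.
#' * `"mspt_degraph"` — like `"gpt"` but without the within-complex binding
#'   edges (subunits of a complex are not linked to each other).
#' * `"mspt_spia"` — like `"gpt"` but compound-mediated interactions are
#'   dropped instead of bridged, so perturbations do not propagate through
#'   non-gene nodes.
#'
#' Pathways containing only gene nodes and no compounds are identical under
#' every strategy. The operation is deterministic and idempotent on such
#' pathways.
#'
#' @param raw A [raw_pathway()].
#' @param strategy One of `"gpt"`, `"mspt_combined"`, `"mspt_degraph"`,
#'   `"mspt_spia"`.
#' @return A [pathway_graph()] with provenance `"GPT"` (for `"gpt"`) or
#'   `"MSPT"`.
#' @export
preprocess_topology <- function(raw,
                                strategy = c("gpt", "mspt_combined",
                                             "mspt_degraph", "mspt_spia")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(raw, "raw_pathway"))
  nodes <- raw$nodes
  edges <- raw$edges
  edges$sign <- if (nrow(edges)) interaction_sign(edges$interaction_type) else integer()

  if (strategy == "mspt_combined") {
    # complexes and families stay as single combined nodes
    keep <- nodes$kind != "compound"
    members <- nodes$members
    is_gene <- nodes$kind == "gene"
    members[is_gene] <- as.list(nodes$node_id[is_gene])
    out_nodes <- tibble(node_id = nodes$node_id, members = members)[keep, ]
    edges <- bridge_compounds(edges, nodes$node_id[nodes$kind == "compound"])
    edges <- canonical_edges(edges, out_nodes$node_id)
    return(pathway_graph(raw$pathway_id, out_nodes, edges, "MSPT"))
  }

  # expand complexes and families to member genes
  expansion <- lapply(seq_len(nrow(nodes)), function(i) {
    k <- nodes$kind[i]
    if (k == "gene") nodes$node_id[i]
    else if (k %in% c("complex", "family")) nodes$members[[i]]
    else character() # compound: handled below
  })
  names(expansion) <- nodes$node_id

  new_edges <- edges
  if (nrow(edges)) {
    pieces <- lapply(seq_len(nrow(edges)), function(i) {
      src <- expansion[[edges$source[i]]]
      tgt <- expansion[[edges$target[i]]]
      if (nodes$kind[match(edges$source[i], nodes$node_id)] == "compound") {
        src <- edges$source[i]
      }
      if (nodes$kind[match(edges$target[i], nodes$node_id)] == "compound") {
        tgt <- edges$target[i]
      }
      expand.grid(source = src, target = tgt,
                  stringsAsFactors = FALSE) |>
        dplyr::mutate(directed = edges$directed[i],
                      interaction_type = edges$interaction_type[i],
                      sign = edges$sign[i])
    })
    new_edges <- dplyr::bind_rows(pieces)
  }

  # within-complex binding edges (the expanded convention only)
  if (strategy %in% c("gpt", "mspt_spia")) {
    cx <- nodes[nodes$kind == "complex", , drop = FALSE]
    if (nrow(cx)) {
      within <- dplyr::bind_rows(lapply(cx$members, function(m) {
        prs <- t(combn(sort(m), 2))
        tibble(source = prs[, 1], target = prs[, 2], directed = FALSE,
               interaction_type = "binding", sign = 0L)
      }))
      new_edges <- dplyr::bind_rows(new_edges, within)
    }
  }

  compounds <- nodes$node_id[nodes$kind == "compound"]
  if (strategy == "mspt_spia") {
    new_edges <- new_edges[!(new_edges$source %in% compounds |
                               new_edges$target %in% compounds), ,
                           drop = FALSE]
  } else {
    new_edges <- bridge_compounds(new_edges, compounds)
  }

  genes <- sort(unique(unlist(expansion, use.names = FALSE)))
  new_edges <- canonical_edges(new_edges, genes)
  pathway_graph(raw$pathway_id, gene_nodes(genes), new_edges,
                if (strategy == "gpt") "GPT" else "MSPT")
}

# Remove compound nodes one at a time, bridging each in-edge to each
# out-edge (undirected incident edges act in both directions). The bridged
# edge inherits the type of whichever constituent hop carries a sign
# (preferring the incoming hop when both do); if neither does, the bridge is
# a neutral "compound" edge. Edges that form cycles passing only through
# compounds collapse to self-loops and are dropped with a warning.
bridge_compounds <- function(edges, compounds) {
  for (cp in compounds) {
    inc <- edges$source == cp | edges$target == cp
    local <- edges[inc, , drop = FALSE]
    edges <- edges[!inc, , drop = FALSE]
    if (!nrow(local)) next
    into <- local[(local$target == cp) | !local$directed, , drop = FALSE]
    outof <- local[(local$source == cp) | !local$directed, , drop = FALSE]
    if (!nrow(into) || !nrow(outof)) next # dangling compound: edges vanish
    bridged <- list()
    for (i in seq_len(nrow(into))) {
      a <- if (into$target[i] == cp) into$source[i] else into$target[i]
      for (j in seq_len(nrow(outof))) {
        b <- if (outof$source[j] == cp) outof$target[j] else outof$source[j]
        if (a == b || a == cp || b == cp) {
          if (a == b) warn(paste0("dropping cycle through compound node ", cp))
          next
        }
        pick <- if (into$sign[i] != 0L) into[i, ] else outof[j, ]
        bridged[[length(bridged) + 1L]] <- tibble(
          source = a, target = b,
          directed = into$directed[i] || outof$directed[j],
          interaction_type = if (pick$sign != 0L) pick$interaction_type
                             else "compound",
          sign = pick$sign
        )
      }
    }
    if (length(bridged)) edges <- dplyr::bind_rows(edges, dplyr::bind_rows(bridged))
  }
  edges
}

# Deduplicate; store undirected edges once with endpoints in sorted order.
canonical_edges <- function(edges, node_ids) {
  if (!nrow(edges)) {
    return(tibble(source = character(), target = character(),
                  directed = logical(), interaction_type = character(),
                  sign = integer()))
  }
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  und <- !edges$directed
  flip <- und & edges$source > edges$target
  tmp <- edges$source[flip]
  edges$source[flip] <- edges$target[flip]
  edges$target[flip] <- tmp
  edges <- dplyr::distinct(edges, .data$source, .data$target, .data$directed,
                           .data$interaction_type, .data$sign)
  edges <- edges[order(edges$source, edges$target, edges$interaction_type), ,
                 drop = FALSE]
  # fresh columns: drop any attributes picked up during expansion
  tibble(source = as.character(edges$source),
         target = as.character(edges$target),
         directed = as.logical(edges$directed),
         interaction_type = as.character(edges$interaction_type),
         sign = as.integer(edges$sign))
}

#' Remove all interactions from a pathway graph
#'
#' The edgeless (gene-set) view of a pathway used by the topology-ablation
#' experiment: the gene set is kept, every interaction is discarded, and
#' provenance becomes `"NOGPT"`. Idempotent.
#'
#' @param g A [pathway_graph()].
#' @return An edgeless [pathway_graph()].
#' @export
strip_interactions <- function(g) {
  pathway_graph(g$pathway_id, g$nodes,
                canonical_edges(g$edges[0, , drop = FALSE], g$nodes$node_id),
                "NOGPT")
}

#' Filter pathways by size and expression coverage
#'
#' Retains pathways with at most `max_genes` genes and at least `min_measured`
#' genes with available expression data; order is preserved.
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param measured_genes Character vector of genes present in the expression
#'   data.
#' @param max_genes Upper size bound (default 150).
#' @param min_measured Minimum measured genes (default 2).
#' @return The retained sublist.
#' @export
filter_pathways <- function(pathways, measured_genes, max_genes = 150,
                            min_measured = 2) {
  keep <- vapply(pathways, function(g) {
    v <- pathway_genes(g)
    length(v) <= max_genes && sum(v %in% measured_genes) >= min_measured
  }, logical(1))
  pathways[keep]
}
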