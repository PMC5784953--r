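# Shared fixtures built in code: tiny gene-only pathways and small
# expression datasets.

gene_only_pathway <- function(id, genes, src = character(), tgt = character(),
                              type = "activation", directed = TRUE) {
  raw_pathway(
    id,
    tibble::tibble(node_id = genes, kind = "gene",
                   members = replicate(length(genes), character(),
                                       simplify = FALSE)),
    tibble::tibble(source = src, target = tgt,
                   directed = rep_len(directed, length(src)),
                   interaction_type = rep_len(type, length(src)))
  )
}

# graph-level constructor for already-preprocessed gene graphs
gene_graph <- function(id, genes, src = character(), tgt = character(),
                       type = "activation", directed = TRUE,
                       provenance = "GPT") {
  e <- tibble::tibble(source = src, target = tgt,
                      directed = rep_len(directed, length(src)),
                      interaction_type = rep_len(type, length(src)))
  e$sign <- if (nrow(e)) {
    tab <- interaction_signs()
    tab$sign[match(e$interaction_type, tab$interaction_type)]
  } else integer()
  pathway_graph(id, tibble::tibble(node_id = genes, members = as.list(genes)),
                e, provenance)
}

# small iid-normal dataset over the given genes (plus optional decoys)
tiny_dataset <- function(genes, n1 = 10, n2 = 10, seed = 1, mu = 7, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(length(genes) * (n1 + n2), mu, sd), length(genes),
              dimnames = list(genes, sprintf("s%02d", seq_len(n1 + n2))))
  expression_dataset(X, rep(c(1L, 2L), c(n1, n2)))
}

# brute-force directed betweenness by path counting (oracle for small graphs)
brute_betweenness <- function(g) {
  ig <- pathwaybench:::pathway_igraph(g, "directed")
  ids <- igraph::V(ig)$name
  btw <- setNames(numeric(length(ids)), ids)
  for (s in ids) for (t in ids) {
    if (s == t) next
    paths <- suppressWarnings(
      igraph::all_shortest_paths(ig, from = s, to = t, mode = "out")$res
    )
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(names(p), c(s, t))
      if (length(inner)) btw[inner] <- btw[inner] + 1 / length(paths)
    }
  }
  btw
}

# brute-force motif enumeration over all k-subsets (oracle for |V| <= 12)
brute_motifs <- function(g, k) {
  ig_und <- pathwaybench:::pathway_igraph(g, "undirected")
  ids <- sort(igraph::V(ig_und)$name)
  subs <- utils::combn(ids, k, simplify = FALSE)
  keep <- Filter(function(s) {
    sub <- igraph::induced_subgraph(ig_und, s)
    igraph::is_connected(sub)
  }, subs)
  lapply(keep, sort)
}
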