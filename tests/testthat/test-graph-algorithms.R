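test_that("centralities match hand calculations on path, star and edgeless graphs", {
  path <- gene_graph("path", c("A", "B", "C"), c("A", "B"), c("B", "C"))
  ct <- node_centralities(path)
  row <- function(g) ct[ct$node_id == g, ]
  expect_equal(row("B")$betweenness, 1)
  expect_equal(row("B")$in_degree, 1L)
  expect_equal(row("A")$out_reach, 2)
  expect_equal(row("C")$in_reach, 2)

  star <- gene_graph("star", c("c", "l1", "l2", "l3", "l4"),
                     rep("c", 4), c("l1", "l2", "l3", "l4"))
  cs <- node_centralities(star)
  expect_equal(cs$out_degree[cs$node_id == "c"], 4L)
  expect_equal(cs$betweenness[cs$node_id == "c"], 0) # no leaf-to-leaf paths

  bare <- gene_graph("bare", c("A", "B", "C"))
  cb <- node_centralities(bare)
  expect_true(all(cb$in_degree == 0 & cb$out_degree == 0 &
                    cb$betweenness == 0 & cb$in_reach == 0 &
                    cb$out_reach == 0))
  expect_true(all(cb$equal_weight == 1))
})

test_that("betweenness equals a brute-force path-counting oracle on random digraphs", {
  for (seed in 1:6) {
    g <- preprocess_topology(
      pathwaybench:::random_dag_pathway("r", 8, default_gene_ids(50), seed,
                                        p_edge = 0.35),
      "gpt")
    ct <- node_centralities(g)
    oracle <- brute_betweenness(g)
    expect_equal(ct$betweenness, unname(oracle[ct$node_id]), tolerance = 1e-9)
  }
})

test_that("clique decomposition reproduces textbook moralization examples", {
  # co-parents A -> C <- B: marrying parents yields one clique {A,B,C}
  vee <- gene_graph("vee", c("A", "B", "C"), c("A", "B"), c("C", "C"))
  d <- decompose_to_cliques(vee)
  expect_equal(d$cliques, list(c("A", "B", "C")))
  expect_equal(d$max_clique_size, 3L)

  # chain: already chordal, cliques are the edges
  chain <- gene_graph("ch", c("A", "B", "C"), c("A", "B"), c("B", "C"))
  dc <- decompose_to_cliques(chain)
  expect_setequal(lapply(dc$cliques, paste, collapse = ","), c("A,B", "B,C"))
  expect_equal(dc$max_clique_size, 2L)

  # edgeless graph: singleton cliques
  bare <- gene_graph("bare", letters[1:5])
  db <- decompose_to_cliques(bare)
  expect_equal(length(db$cliques), 5L)
  expect_true(all(lengths(db$cliques) == 1))
})

test_that("decomposition output is chordal and satisfies the running-intersection property", {
  for (seed in 1:8) {
    g <- preprocess_topology(
      pathwaybench:::random_dag_pathway("r", 12, default_gene_ids(80), seed,
                                        p_edge = 0.25),
      "gpt")
    d <- decompose_to_cliques(g)
    # chordality oracle: igraph maximum-cardinality search
    ig <- igraph::graph_from_adjacency_matrix(d$adjacency, mode = "undirected")
    expect_true(igraph::is_chordal(ig)$chordal)
    # union of cliques covers all nodes; sizes bounded
    expect_setequal(unique(unlist(d$cliques)), d$nodes)
    expect_gte(sum(lengths(d$cliques)), length(d$nodes))
    expect_lte(d$max_clique_size, length(d$nodes))
    # running intersection: each separator is contained in one earlier clique
    if (length(d$cliques) > 1) {
      for (k in 2:length(d$cliques)) {
        sep <- d$separators[[k]]
        expect_equal(sep, sort(intersect(d$cliques[[k]],
                                         unique(unlist(d$cliques[1:(k - 1)])))))
        if (length(sep)) {
          expect_true(any(vapply(d$cliques[1:(k - 1)],
                                 function(cl) all(sep %in% cl), logical(1))))
        }
      }
    }
  }
})

test_that("directed cycles are broken deterministically before moralization", {
  tri <- gene_graph("tri", c("A", "B", "C"), c("A", "B", "C"),
                    c("B", "C", "A"))
  d1 <- decompose_to_cliques(tri)
  d2 <- decompose_to_cliques(tri)
  expect_identical(d1, d2)
  expect_true(length(d1$removed_edges) >= 1)
})

test_that("measured components induce the subgraph on measured genes", {
  g <- gene_graph("g", c("A", "B", "C", "D"),
                  c("A", "C"), c("B", "D"))
  comps <- measured_components(g, c("A", "B", "C", "D"))
  expect_equal(lapply(comps, function(x) sort(x$nodes$node_id)),
               list(c("A", "B"), c("C", "D")))
  # unmeasured middle gene splits a chain
  ch <- gene_graph("ch", c("A", "B", "C"), c("A", "B"), c("B", "C"))
  comps2 <- measured_components(ch, c("A", "C"))
  expect_equal(lapply(comps2, function(x) x$nodes$node_id),
               list("A", "C"))
  # fully connected: one component with all genes and its edges
  comps3 <- measured_components(ch, c("A", "B", "C"))
  expect_equal(length(comps3), 1L)
  expect_equal(nrow(comps3[[1]]$edges), 2L)
})

test_that("motif enumeration matches exhaustive subset enumeration", {
  path4 <- gene_graph("p4", c("A", "B", "C", "D"),
                      c("A", "B", "C"), c("B", "C", "D"))
  m <- enumerate_motifs(path4, 3)
  expect_equal(m$genes, list(c("A", "B", "C"), c("B", "C", "D")))
  expect_equal(length(unique(m$iso_class)), 1L)

  tri <- gene_graph("tri", c("A", "B", "C"), c("A", "B", "C"),
                    c("B", "C", "A"))
  expect_equal(nrow(enumerate_motifs(tri, 3)), 1L)

  for (seed in 1:4) {
    g <- preprocess_topology(
      pathwaybench:::random_dag_pathway("r", 10, default_gene_ids(60), seed,
                                        p_edge = 0.3),
      "gpt")
    for (k in 3:4) {
      got <- enumerate_motifs(g, k)$genes
      oracle <- brute_motifs(g, k)
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(oracle, paste, collapse = ","))
    }
  }
})

test_that("isomorphism classes group instances by directed structure only", {
  # two chains with different signs share a class; a fan-out does not
  g <- gene_graph("g", c("A", "B", "C", "D", "E", "F"),
                  src = c("A", "B", "D", "D"),
                  tgt = c("B", "C", "E", "F"),
                  type = c("activation", "inhibition", "activation",
                           "activation"))
  m <- enumerate_motifs(g, 3)
  cls <- setNames(m$iso_class, vapply(m$genes, paste, character(1),
                                      collapse = ","))
  expect_equal(unname(cls["A,B,C"]) == unname(cls["D,E,F"]), FALSE)
  expect_equal(length(unique(m$iso_class)), 2L)
})
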