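test_that("perturbation propagation reproduces hand examples", {
  ab <- gene_graph("ab", c("A", "B"), "A", "B")
  pr <- spia_propagation(ab, c(A = 1))
  expect_equal(pr$pf, c(A = 1, B = 1))
  expect_equal(pr$acc, c(A = 0, B = 1))
  expect_equal(pr$ta, 1)

  inh <- gene_graph("inh", c("A", "B"), "A", "B", type = "inhibition")
  pr2 <- spia_propagation(inh, c(A = 2))
  expect_equal(pr2$acc[["B"]], -2)

  # linearity: Acc(c * dE) = c * Acc(dE)
  ch <- gene_graph("ch", c("A", "B", "C", "D"), c("A", "B", "C"),
                   c("B", "C", "D"))
  p1 <- spia_propagation(ch, c(A = 1, C = 0.5))
  p3 <- spia_propagation(ch, 3 * c(A = 1, C = 0.5))
  expect_equal(p3$acc, 3 * p1$acc, tolerance = 1e-12)
})

test_that("linear-solve propagation equals damped fixed-point iteration on random DAGs", {
  for (seed in 1:10) {
    g <- preprocess_topology(
      pathwaybench:::random_dag_pathway("r", 12, default_gene_ids(60), seed,
                                        p_edge = 0.25),
      "gpt")
    B <- pathwaybench:::signed_adjacency(g)
    set.seed(seed)
    dE <- stats::rnorm(nrow(B)) * stats::rbinom(nrow(B), 1, 0.3)
    names(dE) <- rownames(B)
    pr <- spia_propagation(g, dE)
    # fixed point: PF = dE + B PF, iterate (converges on DAGs: B nilpotent)
    pf <- dE
    for (i in 1:200) pf <- dE + as.numeric(B %*% pf)
    expect_equal(pr$pf, setNames(pf, rownames(B)), tolerance = 1e-8)
  }
})

test_that("impact-factor test handles boundary p-value cases", {
  # c = 1 => combined p = 1
  cc <- 1
  expect_equal(cc - cc * log(cc), 1)
  # zero DEGs: pG reduces to the hypergeometric p of 1
  genes <- sprintf("g%03d", 1:120)
  d <- tiny_dataset(genes, n1 = 6, n2 = 6, seed = 11)
  g <- gene_graph("p", genes[1:6], genes[1:3], genes[2:4])
  deg <- moderated_t(d)
  deg$p_value[] <- 0.5 # force an empty DEG set
  res <- spia(d, g, deg, method_config(n_permutations = 50, seed = 1))
  expect_equal(res$p_value, 1)
  expect_equal(res$extras[[1]]$pNDE, 1)
  expect_true(is.na(res$extras[[1]]$pPERT))
})

test_that("downstream-DEG score reproduces the chain hand example", {
  genes <- sprintf("g%03d", 1:100)
  d <- tiny_dataset(genes, n1 = 8, n2 = 8, seed = 12)
  chain <- gene_graph("ch", c("A", "B", "C"), c("A", "B"), c("B", "C"))
  dd <- tiny_dataset(c("A", "B", "C", genes), n1 = 8, n2 = 8, seed = 12)
  deg <- moderated_t(dd)
  # force DEGs {A, C} with |logFC| = 1
  deg$p_value[] <- 0.9
  deg$logfc[] <- 0.1
  deg$p_value[deg$gene %in% c("A", "C")] <- 1e-6
  deg$logfc[deg$gene %in% c("A", "C")] <- 1
  res <- prs(dd, chain, deg, method_config(n_permutations = 100, seed = 2))
  # w(A) = 1 + 1 downstream DEG (C), w(C) = 1: score = 1*2 + 1*1 = 3
  expect_equal(res$statistic, 3)

  # edgeless graph: weights are 1, score is the sum of |logFC| over DEGs
  bare <- strip_interactions(chain)
  res2 <- prs(dd, bare, deg, method_config(n_permutations = 100, seed = 2))
  expect_equal(res2$statistic, 2)

  # doubling logFCs doubles the score
  deg2 <- deg
  deg2$logfc <- 2 * deg$logfc
  res3 <- prs(dd, chain, deg2, method_config(n_permutations = 100, seed = 2))
  expect_equal(res3$statistic, 2 * res$statistic)
})

test_that("centrality-weighted scores match the star hand example", {
  genes <- c("c", "l1", "l2", "l3", "l4", sprintf("g%03d", 1:60))
  d <- tiny_dataset(genes, n1 = 6, n2 = 6, seed = 13)
  star <- gene_graph("st", c("c", "l1", "l2", "l3", "l4"),
                     rep("c", 4), c("l1", "l2", "l3", "l4"))
  deg <- moderated_t(d)
  deg$p_value[] <- 0.9
  deg$p_value[deg$gene == "c"] <- 1e-6 # center is the sole DEG
  res <- cepa_ora(d, star, deg, method_config(n_permutations = 100, seed = 3))
  ex <- res$extras[[1]]
  expect_named(ex$centrality_p,
               c("in_degree", "out_degree", "betweenness", "in_reach",
                 "out_reach", "equal_weight"), ignore.order = TRUE)
  # overall p is the uncorrected minimum
  expect_equal(res$p_value, min(unlist(ex$centrality_p)))
  # observed scores: out_degree 4, equal weight 1 (check via internals)
  ns <- pathwaybench:::node_stats(star, deg, call_degs(deg, 0.05))
  ct <- node_centralities(star)
  expect_equal(sum(ct$out_degree[ns$is_deg]), 4)
  expect_equal(sum(ct$equal_weight[ns$is_deg]), 1)
})

test_that("permutation p-values are bounded away from zero", {
  genes <- sprintf("g%03d", 1:80)
  d <- tiny_dataset(genes, n1 = 10, n2 = 10, seed = 14)
  d <- induce_shift(d, perturbation_spec(genes[1:5], 3, 2L))
  g <- gene_graph("p", genes[1:5], genes[1:4], genes[2:5])
  cfg <- method_config(n_permutations = 50, seed = 4)
  for (m in c("prs", "cepa")) {
    res <- run_method(m, d, list(g), cfg)
    expect_gte(res$p_value, 1 / 51)
    expect_lte(res$p_value, 1)
  }
})

test_that("competitive tests react to decoy background genes, self-contained tests do not", {
  genes <- sprintf("g%03d", 1:60)
  pg <- genes[1:8]
  d_small <- tiny_dataset(genes, n1 = 10, n2 = 10, seed = 15)
  d_small <- induce_shift(d_small, perturbation_spec(pg[1:4], 1.5, 2L))
  # same pathway data, universe enlarged with pure-noise decoys
  set.seed(99)
  decoys <- matrix(rnorm(500 * 20, 7, 1), 500,
                   dimnames = list(sprintf("d%03d", 1:500),
                                   colnames(d_small$X)))
  d_big <- expression_dataset(rbind(d_small$X, decoys), d_small$y)
  g <- gene_graph("p", pg, pg[1:7], pg[2:8])
  cfg <- method_config(n_permutations = 200, seed = 5)
  # self-contained statistics are invariant to the decoys
  for (m in c("tappa", "topologygsa", "clipper", "degraph")) {
    r1 <- run_method(m, d_small, list(g), cfg)
    r2 <- run_method(m, d_big, list(g), cfg)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9,
                 label = paste(m, "statistic"))
  }
  # the hypergeometric component of the competitive test shifts
  deg_s <- moderated_t(d_small); deg_b <- moderated_t(d_big)
  r_s <- spia(d_small, g, deg_s, cfg)
  r_b <- spia(d_big, g, deg_b, cfg)
  expect_false(isTRUE(all.equal(r_s$extras[[1]]$pNDE, r_b$extras[[1]]$pNDE)))
})
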