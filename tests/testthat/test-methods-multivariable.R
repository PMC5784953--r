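test_that("constrained covariance reproduces sample clique marginals", {
  for (seed in 1:6) {
    g <- preprocess_topology(
      pathwaybench:::random_dag_pathway("r", 10, default_gene_ids(50), seed,
                                        p_edge = 0.3),
      "gpt")
    dec <- decompose_to_cliques(g)
    str <- pathwaybench:::ggm_structure(dec)
    set.seed(seed)
    Z <- matrix(rnorm(30 * length(dec$nodes)), 30)
    colnames(Z) <- dec$nodes
    S <- pathwaybench:::cov_ml(Z)
    K <- pathwaybench:::ggm_precision(S, str)
    Sig <- solve(K)
    dimnames(Sig) <- dimnames(S)
    for (cl in dec$cliques) {
      expect_equal(Sig[cl, cl], S[cl, cl], tolerance = 1e-8)
    }
    # log-likelihood determinant identity
    ms <- pathwaybench:::margin_stats(S, str)
    expect_equal(ms$ld, determinant(Sig)$modulus[[1]], tolerance = 1e-8)
  }
})

test_that("clique-size precondition decides testability of the GGM test", {
  # 6-gene clique (complete graph) vs chain, group sizes straddling the bound
  genes <- sprintf("q%02d", 1:6)
  prs_idx <- t(utils::combn(genes, 2))
  cliq <- gene_graph("cliq", genes, prs_idx[, 1], prs_idx[, 2],
                     directed = FALSE, type = "binding")
  d_small <- tiny_dataset(genes, n1 = 6, n2 = 5, seed = 20) # 5 <= 6
  d_big <- tiny_dataset(genes, n1 = 10, n2 = 8, seed = 20) # 8 > 6
  cfg <- method_config(n_permutations = 50, seed = 6)
  expect_equal(topology_gsa(d_small, cliq, cfg)$status, "not_testable")
  expect_equal(topology_gsa(d_big, cliq, cfg)$status, "ok")
})

test_that("shrinkage-free limit of the shrinkage test matches the ML test", {
  genes <- sprintf("q%02d", 1:8)
  g <- gene_graph("g", genes, genes[1:7], genes[2:8])
  d <- tiny_dataset(genes, n1 = 40, n2 = 40, seed = 21)
  cfg0 <- method_config(n_permutations = 30, seed = 7, clipper_lambda = 0)
  cfg1 <- method_config(n_permutations = 30, seed = 7)
  r_cl <- clipper(d, g, cfg0)
  r_tg <- topology_gsa(d, g, cfg1)
  expect_equal(r_cl$statistic, r_tg$statistic, tolerance = 1e-6)
  expect_equal(r_cl$p_value, r_tg$p_value, tolerance = 1e-12)
})

test_that("shrinkage keeps large cliques testable where the ML test fails", {
  genes <- sprintf("q%02d", 1:30)
  prs_idx <- t(utils::combn(genes, 2))
  cliq30 <- gene_graph("cliq30", genes, prs_idx[, 1], prs_idx[, 2],
                       directed = FALSE, type = "binding")
  d <- tiny_dataset(genes, n1 = 10, n2 = 10, seed = 22)
  cfg <- method_config(n_permutations = 30, seed = 8)
  expect_equal(topology_gsa(d, cliq30, cfg)$status, "not_testable")
  r <- clipper(d, cliq30, cfg)
  expect_equal(r$status, "ok")
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("estimated shrinkage intensity is sane and shrinks correlations", {
  set.seed(23)
  Z <- matrix(rnorm(15 * 10), 15, 10)
  Ss <- pathwaybench:::shrink_cov(Z)
  lam <- attr(Ss, "lambda")
  expect_true(lam > 0 && lam <= 1)
  S <- pathwaybench:::cov_ml(Z)
  expect_equal(diag(Ss), diag(S), tolerance = 1e-12)
  off <- upper.tri(S)
  expect_true(all(abs(Ss[off]) <= abs(S[off]) + 1e-12))
  expect_equal(shrink_cov_lambda0 <- pathwaybench:::shrink_cov(Z, 0), S,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("full spectral basis recovers classical Hotelling exactly", {
  for (seed in 1:6) {
    m <- sample(3:6, 1)
    genes <- sprintf("q%02d", seq_len(m))
    g <- gene_graph("g", genes, genes[-m], genes[-1]) # chain component
    d <- tiny_dataset(genes, n1 = 12, n2 = 10, seed = 30 + seed)
    cfg <- method_config(degraph_k_fraction = 1)
    r <- degraph(d, g, cfg)
    # classical two-sample Hotelling T2 on the raw data
    X1 <- t(d$X[genes, d$y == 1]); X2 <- t(d$X[genes, d$y == 2])
    n1 <- nrow(X1); n2 <- nrow(X2); n <- n1 + n2
    dm <- colMeans(X2) - colMeans(X1)
    Sp <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n - 2)
    t2 <- (n1 * n2 / n) * drop(t(dm) %*% solve(Sp, dm))
    f <- (n - m - 1) / ((n - 2) * m) * t2
    p_cls <- stats::pf(f, m, n - m - 1, lower.tail = FALSE)
    expect_equal(r$statistic, t2, tolerance = 1e-10)
    expect_equal(r$p_value, p_cls, tolerance = 1e-10)
  }
})

test_that("single-edge component has Laplacian spectrum {0, 2} and averaged projection", {
  g <- gene_graph("e", c("A", "B"), "A", "B", directed = FALSE,
                  type = "binding")
  A <- matrix(c(0, 1, 1, 0), 2)
  L <- diag(c(1, 1)) - A
  ev <- eigen(L, symmetric = TRUE)
  expect_equal(sort(ev$values), c(0, 2))
  # smoothest eigenvector is the constant vector: projection (xA + xB)/sqrt(2)
  d <- tiny_dataset(c("A", "B"), n1 = 10, n2 = 10, seed = 24)
  r <- degraph(d, g, method_config(degraph_k_fraction = 0.2)) # k = 1
  proj <- (d$X["A", ] + d$X["B", ]) / sqrt(2)
  tt <- stats::t.test(proj[d$y == 2], proj[d$y == 1], var.equal = TRUE)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("component aggregation is Bonferroni over measured components", {
  g <- gene_graph("two", c("A", "B", "C", "D"), c("A", "C"), c("B", "D"))
  d <- tiny_dataset(c("A", "B", "C", "D"), n1 = 10, n2 = 10, seed = 25)
  r <- degraph(d, g, method_config(degraph_k_fraction = 1))
  comp_p <- unlist(r$extras[[1]]$component_p)
  expect_equal(r$p_value, min(1, min(comp_p) * 2), tolerance = 1e-12)
})

test_that("edgeless-pathway connectivity index reduces to the mean absolute z-score", {
  genes <- sprintf("q%02d", 1:7)
  bare <- gene_graph("bare", genes)
  d <- tiny_dataset(genes, n1 = 8, n2 = 8, seed = 26)
  pci <- tappa_pci(d, bare)
  z <- t(scale(t(d$X[genes, ])))
  expect_equal(pci, colSums(abs(z)) / length(genes), tolerance = 1e-12)
})

test_that("connectivity-index values ignore group labels; only the test changes", {
  genes <- sprintf("q%02d", 1:6)
  g <- gene_graph("g", genes, genes[1:5], genes[2:6])
  d <- tiny_dataset(genes, n1 = 8, n2 = 8, seed = 27)
  relab <- null_relabel(d, seed = 3)
  expect_equal(tappa_pci(d, g), tappa_pci(relab, g))
  r1 <- tappa(d, g)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  # identical PCI distributions in both groups give p near 1
  dsym <- d
  dsym$X[] <- rep(dsym$X[, 1:8], 2) # group 2 duplicates group 1
  r2 <- tappa(dsym, g)
  expect_gt(r2$p_value, 0.9)
})

test_that("batched permutation statistics match the per-label path exactly", {
  set.seed(31)
  for (seed in c(3, 4, 6)) {
    g <- preprocess_topology(
      pathwaybench:::random_dag_pathway("r", 6, default_gene_ids(40), seed,
                                        p_edge = 0.25),
      "gpt")
    dec <- decompose_to_cliques(g)
    str <- pathwaybench:::ggm_structure(dec)
    # batched path applies when all margins have size <= 2; these seeds do
    expect_equal(length(str$multi), 0L)
    n1 <- 12; n2 <- 9
    Z <- matrix(rnorm((n1 + n2) * length(dec$nodes)), n1 + n2)
    colnames(Z) <- dec$nodes
    y <- rep(c(1L, 2L), c(n1, n2))
    P <- replicate(15, sample(y) == 1L)
    cases <- list(list(shrink = FALSE, lambda = NULL,
                       est = pathwaybench:::cov_ml),
                  list(shrink = TRUE, lambda = NULL,
                       est = function(Zg) pathwaybench:::shrink_cov(Zg)),
                  list(shrink = TRUE, lambda = 0.3,
                       est = function(Zg) pathwaybench:::shrink_cov(Zg, 0.3)))
    for (cs in cases) {
      loop <- sapply(seq_len(ncol(P)), function(b) {
        pathwaybench:::ggm_step_stats(Z, P[, b], str, cs$est)
      })
      bat <- pathwaybench:::ggm_step_stats_batched(Z, P, str, n1, n2,
                                                   shrink = cs$shrink,
                                                   lambda = cs$lambda)
      expect_equal(loop, bat, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})
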