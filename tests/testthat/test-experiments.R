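# Experiment configurations here are deliberately tiny: the goal is the
# bookkeeping contracts, not statistical power (the calibration and
# sensitivity checks live in the acceptance suite).

small_bench <- function() {
  genes <- sprintf("g%03d", 1:150)
  d <- tiny_dataset(genes, n1 = 12, n2 = 12, seed = 60)
  pws <- list(gene_graph("a", genes[1:6], genes[1:5], genes[2:6]),
              gene_graph("b", genes[7:46]))
  list(d = d, pws = pws)
}

test_that("DEP proportion counts testable rows only", {
  res <- tibble::tibble(p_value = c(0.01, 0.2, 0.9, NA),
                        status = c("ok", "ok", "ok", "not_testable"))
  expect_equal(as.numeric(dep_proportion(res, 0.05)), 1 / 3)
  expect_equal(attr(dep_proportion(res, 0.05), "n_not_testable"), 1L)
  expect_equal(as.numeric(dep_proportion(res, 1)), 1)
  # monotone in alpha
  alphas <- c(0.001, 0.01, 0.05, 0.5, 1)
  props <- vapply(alphas, function(a) as.numeric(dep_proportion(res, a)),
                  numeric(1))
  expect_true(all(diff(props) >= 0))
  all_nt <- tibble::tibble(p_value = NA_real_, status = "not_testable")
  expect_warning(out <- dep_proportion(all_nt), "undefined")
  expect_true(is.na(out))
})

test_that("influence categories use half-open bins closed at 1", {
  expect_equal(as.character(categorize_influence(c(0, 0.19, 0.2, 0.35, 0.4,
                                                   0.6, 0.79, 0.8, 1))),
               c("very_low", "very_low", "low", "low", "medium", "high",
                 "high", "very_high", "very_high"))
})

test_that("dense ranks follow the tie-aware convention", {
  expect_equal(dense_ranks(c(0.01, 0.01, 0.02)), c(1L, 1L, 2L))
  expect_equal(dense_ranks(c(0.5, 0.1, 0.9)), c(2L, 1L, 3L))
  expect_equal(dense_ranks(rep(0.3, 4)), rep(1L, 4))
})

test_that("sample-size experiment produces the documented summaries", {
  b <- small_bench()
  rep <- ex1_sample_size(b$d, b$pws, c("tappa", "prs"),
                         fractions = c(0.5, 1), n_subsets = 2,
                         thresholds = c(0.05, 0.01),
                         cfg = method_config(n_permutations = 30, seed = 61))
  s <- glance(rep, "dep_by_fraction")
  expect_setequal(names(s), c("method", "fraction", "median_dep_prop"))
  expect_equal(nrow(s), 4) # 2 methods x 2 fractions
  # size strata: pathway a (6 genes) small, b (40 genes) large
  bs <- glance(rep, "by_size")
  expect_setequal(unique(bs$size_class), c("small", "large"))
  # threshold sweep only for the DEG-based method
  bt <- glance(rep, "by_threshold")
  expect_setequal(unique(bt$method), "prs")
  expect_setequal(unique(bt$theta), c(0.05, 0.01))
  # summaries recomputable from rows
  rows <- tidy(rep)
  manual <- rows |>
    dplyr::filter(.data$method == "tappa", .data$fraction == 1)
  expect_equal(s$median_dep_prop[s$method == "tappa" & s$fraction == 1],
               median(tapply(manual$p_value < 0.05, manual$subset, mean)))
})

test_that("type-I-error experiment reports rates and a complete histogram", {
  b <- small_bench()
  rep <- ex2_type1(b$d, b$pws, c("tappa", "degraph"), n_tests = 10,
                   cfg = method_config(seed = 62))
  t1 <- glance(rep, "type1")
  expect_setequal(t1$method, c("tappa", "degraph"))
  expect_true(all(t1$n_tested == 10))
  hist <- glance(rep, "histogram")
  sums <- tapply(hist$count, hist$method, sum)
  expect_true(all(sums == 10))
  # deterministic: same seed reproduces the report
  rep2 <- ex2_type1(b$d, b$pws, c("tappa", "degraph"), n_tests = 10,
                    cfg = method_config(seed = 62))
  expect_identical(tidy(rep)$p_value, tidy(rep2)$p_value)
})

test_that("single-gene influence report pools increments and replicates", {
  dcfg <- synthetic_config(n_genes = 200, n1 = 15, n2 = 10, seed = 63)
  pw <- gene_graph("ch", default_gene_ids(200)[1:4],
                   default_gene_ids(200)[1:3], default_gene_ids(200)[2:4])
  rep <- ex3_single_gene(dcfg, pw, "tappa", deltas = c(0.5, 2),
                         n_datasets = 2,
                         cfg = method_config(seed = 64))
  rows <- tidy(rep)
  expect_equal(nrow(rows), 4 * 2 * 2) # genes x deltas x replicates
  inf <- glance(rep, "influence")
  expect_equal(nrow(inf), 4)
  expect_true(all(inf$influence >= 0 & inf$influence <= 1))
  # influence equals the pooled mean of the dep flags
  g1 <- rows$gene[1]
  expect_equal(inf$influence[inf$gene == g1],
               mean(rows$dep[rows$gene == g1]))
  curve <- glance(rep, "curve")
  expect_equal(nrow(curve), 2)
})

test_that("gene-set experiment ties influence back to single-gene results", {
  dcfg <- synthetic_config(n_genes = 150, n1 = 12, n2 = 8, seed = 65)
  genes <- default_gene_ids(150)[1:5]
  pw <- gene_graph("ch", genes, genes[1:4], genes[2:5])
  single <- tibble::tibble(method = "tappa", gene = genes,
                           influence = c(0.1, 0.2, 0.3, 0.4, 0.5))
  rep <- ex4_gene_sets(dcfg, pw, "tappa", set_sizes = c(2, 3), n_sets = 2,
                       deltas = c(1), n_datasets = 2,
                       cfg = method_config(seed = 66),
                       single_influence = single)
  inf <- glance(rep, "influence")
  expect_equal(nrow(inf), 4) # 2 sizes x 2 sets
  expect_true(all(c("member_influence_sum", "category") %in% names(inf)))
  # member sums match the supplied single-gene influences
  sets <- rep$summary$sets
  for (i in seq_len(nrow(sets))) {
    expected <- sum(single$influence[single$gene %in% sets$genes[[i]]])
    got <- inf$member_influence_sum[inf$set_id == sets$set_id[i]]
    expect_equal(got, expected)
  }
  expect_equal(nrow(tidy(rep)), 4 * 1 * 2) # sets x deltas x replicates
})

test_that("motif experiment contrasts motifs against size-matched random sets", {
  dcfg <- synthetic_config(n_genes = 150, n1 = 12, n2 = 8, seed = 67)
  genes <- default_gene_ids(150)[1:6]
  pw <- gene_graph("g", genes, genes[c(1, 2, 3, 4, 5)],
                   genes[c(2, 3, 4, 5, 6)])
  rep <- ex5_motifs(dcfg, pw, "tappa", k_values = 3, deltas = c(1),
                    n_datasets = 1, cfg = method_config(seed = 68),
                    max_per_class = 2, n_random = 2)
  inf <- glance(rep, "influence")
  expect_setequal(unique(inf$kind), c("motif", "random"))
  expect_true(all(inf$set_size == 3))
  ctr <- glance(rep, "contrast")
  expect_setequal(names(ctr),
                  c("method", "kind", "set_size", "delta", "dep_prop"))
})

test_that("target ranking excludes untestable targets and medians the rest", {
  res <- tibble::tibble(
    method = "m",
    dataset = rep(c("d1", "d2"), each = 3),
    pathway_id = rep(c("t", "x", "y"), 2),
    p_value = c(0.01, 0.02, 0.02, NA, 0.5, 0.6),
    status = c("ok", "ok", "ok", "not_testable", "ok", "ok")
  )
  rep <- ex6_target_rank(res, "t")
  tg <- glance(rep, "targets")
  expect_equal(tg$median_rank, 1) # unique lowest p in d1
  expect_equal(nrow(rep$summary$not_testable), 1)
  # ties: all equal p-values share rank 1
  res2 <- res[1:3, ]; res2$p_value <- 0.3
  expect_true(all(tidy(ex6_target_rank(res2, c("t", "x", "y")))$rank == 1))
})

test_that("ablation pairs every method-pathway combination", {
  b <- small_bench()
  rep <- ex7_ablation(b$d, b$pws, c("prs", "clipper"),
                      cfg = method_config(n_permutations = 30, seed = 69))
  paired <- glance(rep, "paired")
  expect_equal(nrow(paired), 4) # 2 methods x 2 pathways
  expect_true(all(c("p_topology", "p_edgeless", "p_diff") %in% names(paired)))
})

test_that("pre-processing contrast is a no-op on gene-only pathways", {
  genes <- sprintf("g%03d", 1:40)
  d <- tiny_dataset(genes, n1 = 10, n2 = 10, seed = 70)
  raw <- list(gene_only_pathway("p", genes[1:5], genes[1:4], genes[2:5]))
  rep <- ex8_preprocessing(d, raw, c("prs", "tappa"),
                           cfg = method_config(n_permutations = 30, seed = 71))
  paired <- glance(rep, "paired")
  pr <- paired[paired$method == "prs", ]
  expect_equal(pr$p_gpt, pr$p_mspt)
  # method without a distinct original convention runs on gpt only
  tp <- paired[paired$method == "tappa", ]
  expect_false("p_mspt" %in% names(tp) && !all(is.na(tp$p_mspt)))
})

test_that("rejection rates respond monotonically to the induced shift at reduced replication", {
  pathways <- benchmark_pathway_suite(1)
  dcfg <- synthetic_config(seed = 90)
  cfg <- method_config(n_permutations = 100, seed = 91)
  methods <- c("spia", "prs", "cepa", "tappa", "topologygsa", "clipper",
               "degraph")
  rep <- ex3_single_gene(dcfg, pathways$chain, methods,
                         deltas = c(0.5, 1, 2), n_datasets = 5, cfg = cfg)
  curve <- glance(rep, "curve")
  for (m in methods) {
    cm <- curve[curve$method == m, ]
    lo <- cm$dep_prop[cm$delta == 0.5]
    hi <- cm$dep_prop[cm$delta == 2]
    se <- sqrt(pmax(lo * (1 - lo), 0.25 / 25) / 25)
    expect_gte(hi, lo - 2 * se)
  }
})
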