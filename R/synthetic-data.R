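#' Configuration for the synthetic expression generator
#'
#' The generator emulates a large two-group breast-tumour microarray matrix
#' on the log2 scale: per-gene means and standard deviations drawn from
#' wide distributions, genes organized into correlation blocks of
#' co-regulated genes, and an unbalanced two-group design. Defaults are
#' sized for desk-scale benchmarking: a 2 000-gene universe, a 120/60
#' split (an estrogen-receptor-status-like imbalance), blocks of 20 genes
#' with within-block correlation 0.2, gene means ~ Normal(7, 2^2) and gene
#' SDs ~ |Normal(0.5, 0.25^2)| + 0.1. Both groups are drawn from the same
#' distribution; any group effect is injected afterwards with
#' [induce_shift()].
#'
#' @param n_genes Universe size (controls "platform density").
#' @param n1,n2 Group sizes.
#' @param block_size Genes per correlation block.
#' @param rho Within-block correlation; values outside the positive-definite
#'   range are clipped with a warning.
#' @param mean_mean,mean_sd Distribution of per-gene means (log2 scale).
#' @param sd_mean,sd_sd,sd_min Distribution of per-gene SDs:
#'   `|Normal(sd_mean, sd_sd^2)| + sd_min`.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n1 = 120, n2 = 60,
                             block_size = 20, rho = 0.2,
                             mean_mean = 7, mean_sd = 2,
                             sd_mean = 0.5, sd_sd = 0.25, sd_min = 0.1,
                             seed = 1) {
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default synthetic gene universe
#'
#' Gene identifiers used by the generator and the toy pathway fixtures
#' (opaque Entrez-style strings).
#'
#' @param n Number of genes.
#' @return Character vector `g0001 ... g<n>`.
#' @export
default_gene_ids <- function(n = 2000) sprintf("g%04d", seq_len(n))

#' Generate a synthetic two-group expression dataset
#'
#' Draws a multivariate-normal log2 matrix under the global null: per-gene
#' means and SDs from the configured distributions, compound-symmetric
#' correlation `rho` within consecutive blocks of `block_size` genes, and
#' independent blocks. Both groups follow the identical distribution.
#'
#' @param cfg A [synthetic_config()].
#' @return An [expression_dataset()] with genes named by
#'   [default_gene_ids()].
#' @export
generate_base_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    p <- cfg$n_genes
    n <- cfg$n1 + cfg$n2
    rho <- cfg$rho
    b <- min(cfg$block_size, p)
    lo <- if (b > 1) -1 / (b - 1) + 1e-6 else 0
    if (rho < lo || rho > 1 - 1e-12) {
      rho_new <- min(max(rho, lo), 1 - 1e-6)
      warn(sprintf("rho = %g makes blocks non-positive-definite; clipped to %g",
                   rho, rho_new))
      rho <- rho_new
    }
    mu <- rnorm(p, cfg$mean_mean, cfg$mean_sd)
    sds <- abs(rnorm(p, cfg$sd_mean, cfg$sd_sd)) + cfg$sd_min
    block <- rep(seq_len(ceiling(p / b)), each = b)[seq_len(p)]
    Z <- matrix(rnorm(p * n), p, n)
    if (rho != 0) {
      Sigma <- matrix(rho, b, b); diag(Sigma) <- 1
      Lt <- chol(Sigma) # t(Lt) %*% z has the block correlation
      for (bl in unique(block)) {
        idx <- which(block == bl)
        if (length(idx) == b) {
          Z[idx, ] <- crossprod(Lt, Z[idx, , drop = FALSE])
        } else if (length(idx) > 1) {
          Sg <- matrix(rho, length(idx), length(idx)); diag(Sg) <- 1
          Z[idx, ] <- crossprod(chol(Sg), Z[idx, , drop = FALSE])
        }
      }
    }
    X <- mu + sds * Z
    rownames(X) <- default_gene_ids(p)
    colnames(X) <- sprintf("s%03d", seq_len(n))
    expression_dataset(X, rep(c(1L, 2L), c(cfg$n1, cfg$n2)))
  })
}

#' Specify an induced expression shift
#'
#' @param genes Non-empty character vector of genes to shift.
#' @param delta Non-negative log2 shift.
#' @param group Target group (1 or 2); default 1.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(genes, delta, group = 1L) {
  stopifnot(length(genes) >= 1, delta >= 0, group %in% c(1L, 2L))
  structure(list(genes = genes, delta = delta, group = as.integer(group)),
            class = "perturbation_spec")
}

#' Add a group-specific expression shift
#'
#' Adds `delta` (log2 units) to the specified genes in every sample of the
#' target group; all other entries are untouched, so the realized group
#' mean difference of a shifted gene changes by exactly `delta`.
#'
#' @param data An [expression_dataset()].
#' @param spec A [perturbation_spec()].
#' @return The shifted [expression_dataset()].
#' @export
induce_shift <- function(data, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  missing <- setdiff(spec$genes, rownames(data$X))
  if (length(missing)) {
    abort(paste0("unknown gene(s): ", paste(missing, collapse = ", ")))
  }
  data$X[spec$genes, data$y == spec$group] <-
    data$X[spec$genes, data$y == spec$group] + spec$delta
  data
}

#' Permute group labels
#'
#' Uniform random relabeling preserving the group sizes; the expression
#' matrix is untouched. Used to manufacture null hypotheses on real-like
#' data.
#'
#' @param data An [expression_dataset()].
#' @param seed Integer seed.
#' @return The relabeled [expression_dataset()].
#' @export
null_relabel <- function(data, seed = NULL) {
  with_seed(seed, {
    data$y <- sample(data$y)
    data
  })
}

#' Subsample a dataset preserving group proportions
#'
#' Keeps `floor(fraction * group size)` samples per group, drawn without
#' replacement.
#'
#' @param data An [expression_dataset()].
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled [expression_dataset()].
#' @export
subsample <- function(data, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  k1 <- floor(fraction * data$n1)
  k2 <- floor(fraction * data$n2)
  if (k1 < 2 || k2 < 2) {
    abort(sprintf("fraction %g leaves a group below 2 samples", fraction))
  }
  with_seed(seed, {
    keep <- c(sample(which(data$y == 1L), k1), sample(which(data$y == 2L), k2))
    keep <- sort(keep)
    expression_dataset(data$X[, keep, drop = FALSE], data$y[keep])
  })
}

#' Deterministic toy pathway fixtures
#'
#' Eight small pathways with documented structure, spanning the node kinds
#' and topologies the pre-processing and analysis code must handle: a
#' directed chain, an out-star, a directed triangle (cycle), a DAG with
#' co-parents (moralization adds exactly one edge), a pathway with a
#' 2-subunit complex node, one with a 3-member gene family, one with a
#' compound-bridged interaction, and a 30-gene random DAG. Gene ids are
#' drawn from `universe` (chain/star/etc. use its head; the random DAG
#' samples with the given seed).
#'
#' @param seed Integer seed for the random DAG fixture.
#' @param universe Gene id pool (default [default_gene_ids()]).
#' @return Named list of [raw_pathway()] objects.
#' @export
toy_pathway_suite <- function(seed = 1, universe = default_gene_ids()) {
  gid <- function(i) universe[i]
  g_nodes <- function(ids) tibble(node_id = ids, kind = "gene",
                                  members = replicate(length(ids), character(),
                                                      simplify = FALSE))
  act_edges <- function(src, tgt, type = "activation", directed = TRUE) {
    tibble(source = src, target = tgt, directed = directed,
           interaction_type = type)
  }
  suite <- list()
  # chain g1 -> g2 -> g3 -> g4 -> g5 (activation)
  ch <- gid(1:5)
  suite$chain <- raw_pathway("chain", g_nodes(ch),
                             act_edges(ch[1:4], ch[2:5]))
  # star: center g6 activates 4 leaves
  st <- gid(6:10)
  suite$star <- raw_pathway("star", g_nodes(st),
                            act_edges(rep(st[1], 4), st[2:5]))
  # directed triangle (cycle)
  tr <- gid(11:13)
  suite$triangle <- raw_pathway("triangle", g_nodes(tr),
                                act_edges(tr, tr[c(2, 3, 1)]))
  # co-parent DAG: g14 -> g16 <- g15, g16 -> g17 (moralization marries 14-15)
  cp <- gid(14:17)
  suite$coparent <- raw_pathway("coparent", g_nodes(cp),
                                act_edges(cp[c(1, 2, 3)], cp[c(3, 3, 4)]))
  # complex node {g18, g19} activating g20
  cx <- gid(18:20)
  suite$complex <- raw_pathway(
    "complex",
    dplyr::bind_rows(g_nodes(cx[3]),
                     tibble(node_id = "cplx1", kind = "complex",
                            members = list(cx[1:2]))),
    act_edges("cplx1", cx[3])
  )
  # family node {g21, g22, g23} inhibiting g24
  fm <- gid(21:24)
  suite$family <- raw_pathway(
    "family",
    dplyr::bind_rows(g_nodes(fm[4]),
                     tibble(node_id = "fam1", kind = "family",
                            members = list(fm[1:3]))),
    act_edges("fam1", fm[4], type = "inhibition")
  )
  # compound bridge: g25 -> cpd -> g26
  cb <- gid(25:26)
  suite$compound <- raw_pathway(
    "compound",
    dplyr::bind_rows(g_nodes(cb),
                     tibble(node_id = "cpd1", kind = "compound",
                            members = list(character()))),
    dplyr::bind_rows(act_edges(cb[1], "cpd1"),
                     act_edges("cpd1", cb[2], type = "compound"))
  )
  # 30-gene random DAG over a seeded sample of the universe
  suite$random_dag <- random_dag_pathway("random_dag", 30, universe,
                                         seed = seed, p_edge = 0.08,
                                         skip = 26)
  suite
}

# Random DAG raw pathway: genes sampled from the universe (after `skip`
# reserved ids), edges only forward in a random order, signs mixed.
random_dag_pathway <- function(pathway_id, n_genes, universe, seed,
                               p_edge = 0.08, skip = 0) {
  with_seed(seed, {
    pool <- universe[(skip + 1):length(universe)]
    ids <- sort(sample(pool, n_genes))
    ord <- sample(ids)
    pairs <- t(combn(seq_len(n_genes), 2))
    take <- runif(nrow(pairs)) < p_edge
    pairs <- pairs[take, , drop = FALSE]
    types <- sample(c("activation", "inhibition", "binding"), nrow(pairs),
                    replace = TRUE, prob = c(0.6, 0.25, 0.15))
    edges <- tibble(source = ord[pairs[, 1]], target = ord[pairs[, 2]],
                    directed = types != "binding", interaction_type = types)
    nodes <- tibble(node_id = ids, kind = "gene",
                    members = replicate(n_genes, character(),
                                        simplify = FALSE))
    raw_pathway(pathway_id, nodes, edges)
  })
}

#' Benchmark pathway collection
#'
#' The eight canonical fixtures of [toy_pathway_suite()] plus twelve seeded
#' random DAG pathways of 10 to 60 genes — a 20-pathway collection with a
#' realistic spread of sizes for calibration and sensitivity benchmarks.
#' All pathways are pre-processed with [preprocess_topology()] under the
#' expanded (`"gpt"`) convention.
#'
#' @param seed Integer seed.
#' @param universe Gene id pool.
#' @return Named list of 20 [pathway_graph()] objects.
#' @export
benchmark_pathway_suite <- function(seed = 1, universe = default_gene_ids()) {
  raw <- toy_pathway_suite(seed, universe)
  sizes <- round(seq(10, 60, length.out = 12))
  extra <- lapply(seq_along(sizes), function(i) {
    random_dag_pathway(sprintf("dag%02d", i), sizes[i], universe,
                       seed = seed + 100 + i, p_edge = 2.5 / sizes[i],
                       skip = 60)
  })
  names(extra) <- vapply(extra, function(p) p$pathway_id, character(1))
  lapply(c(raw, extra), preprocess_topology, strategy = "gpt")
}
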