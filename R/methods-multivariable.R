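# Two-step decomposable-GGM tests (TopologyGSA, Clipper) and the
# graph-Laplacian Fourier Hotelling test (DEGraph).

# ML covariance (denominator n), rows = samples.
cov_ml <- function(Z) {
  n <- nrow(Z)
  mu <- colMeans(Z)
  crossprod(Z) / n - tcrossprod(mu)
}

# James-Stein-type shrinkage of the ML covariance towards its diagonal:
# correlations are shrunk by the closed-form intensity
# lambda = sum Var(r_ij) / sum r_ij^2 (clipped to [0, 1]), variances kept.
shrink_cov <- function(Z, lambda = NULL) {
  n <- nrow(Z)
  S <- cov_ml(Z)
  v <- diag(S)
  v[v <= 0] <- .Machine$double.eps
  sdv <- sqrt(v)
  R <- S / tcrossprod(sdv)
  if (is.null(lambda)) {
    p <- ncol(Z)
    Zs <- (Z - rep(colMeans(Z), each = n)) * rep(1 / sdv, each = n)
    # Var-hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - mean w_ij)^2,
    # with w_kij = z_ki z_kj
    sw <- crossprod(Zs) # sum_k w_kij = n * r_ij (ML-standardized)
    sw2 <- crossprod(Zs^2)
    varr <- n / (n - 1)^3 * (sw2 - sw^2 / n)
    diag(varr) <- 0
    off <- R; diag(off) <- 0
    denom <- sum(off^2)
    lambda <- if (denom > 0) sum(varr) / denom else 1
    lambda <- min(1, max(0, lambda))
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  Ss <- Rs * tcrossprod(sdv)
  attr(Ss, "lambda") <- lambda
  Ss
}

# Margin index structure of a clique decomposition: singleton margins are
# handled vectorized, larger ones by Cholesky. Indices are positions in
# decomp$nodes.
ggm_structure <- function(decomp) {
  ids <- decomp$nodes
  margins <- c(lapply(decomp$cliques, function(cl) list(idx = match(cl, ids),
                                                        sign = 1)),
               lapply(decomp$separators[lengths(decomp$separators) > 0],
                      function(sp) list(idx = match(sp, ids), sign = -1)))
  sizes <- vapply(margins, function(m) length(m$idx), integer(1))
  sing <- margins[sizes == 1]
  pairs <- margins[sizes == 2]
  p <- length(ids)
  sing_idx <- vapply(sing, function(m) m$idx, integer(1))
  pair_i <- vapply(pairs, function(m) m$idx[1], integer(1))
  pair_j <- vapply(pairs, function(m) m$idx[2], integer(1))
  list(
    p = p,
    sing_idx = sing_idx,
    sing_sign = vapply(sing, function(m) m$sign, numeric(1)),
    sing_lin = (sing_idx - 1L) * p + sing_idx, # linear index into p x p S
    pair_i = pair_i,
    pair_j = pair_j,
    pair_sign = vapply(pairs, function(m) m$sign, numeric(1)),
    pair_ii = (pair_i - 1L) * p + pair_i,
    pair_jj = (pair_j - 1L) * p + pair_j,
    pair_ij = (pair_j - 1L) * p + pair_i,
    multi = margins[sizes > 2]
  )
}

# log det Sigma-hat under the decomposable model (sum over signed margins)
# and, optionally, the quadratic form d' K d. Size-1 and size-2 margins in
# closed form, vectorized; larger margins by Cholesky. NULL when a margin
# is singular.
margin_stats <- function(S, str, d = NULL) {
  ld <- 0; quad <- 0
  if (length(str$sing_idx)) {
    v <- S[str$sing_lin]
    if (any(v <= 0)) return(NULL)
    ld <- sum(str$sing_sign * log(v))
    if (!is.null(d)) quad <- sum(str$sing_sign * d[str$sing_idx]^2 / v)
  }
  if (length(str$pair_i)) {
    v1 <- S[str$pair_ii]
    v2 <- S[str$pair_jj]
    cv <- S[str$pair_ij]
    det2 <- v1 * v2 - cv^2
    if (any(det2 <= 0) || any(v1 <= 0)) return(NULL)
    ld <- ld + sum(str$pair_sign * log(det2))
    if (!is.null(d)) {
      d1 <- d[str$pair_i]; d2 <- d[str$pair_j]
      quad <- quad +
        sum(str$pair_sign * (d1^2 * v2 - 2 * d1 * d2 * cv + d2^2 * v1) / det2)
    }
  }
  if (length(str$multi)) {
    res <- tryCatch({
      for (m in str$multi) {
        L <- chol(S[m$idx, m$idx])
        ld <- ld + m$sign * 2 * sum(log(diag(L)))
        if (!is.null(d)) {
          u <- backsolve(L, d[m$idx], transpose = TRUE)
          quad <- quad + m$sign * sum(u^2)
        }
      }
      TRUE
    }, error = function(e) FALSE)
    if (!res) return(NULL)
  }
  list(ld = ld, quad = quad)
}

# Assemble the constrained precision K = sum_margins sign * [S_mm^-1]^0.
ggm_precision <- function(S, str) {
  K <- matrix(0, str$p, str$p)
  if (length(str$sing_idx)) {
    v <- S[cbind(str$sing_idx, str$sing_idx)]
    if (any(v <= 0)) return(NULL)
    for (i in seq_along(str$sing_idx)) {
      j <- str$sing_idx[i]
      K[j, j] <- K[j, j] + str$sing_sign[i] / v[i]
    }
  }
  for (k in seq_along(str$pair_i)) {
    i <- str$pair_i[k]; j <- str$pair_j[k]
    det2 <- S[i, i] * S[j, j] - S[i, j]^2
    if (det2 <= 0) return(NULL)
    s <- str$pair_sign[k] / det2
    K[i, i] <- K[i, i] + s * S[j, j]
    K[j, j] <- K[j, j] + s * S[i, i]
    K[i, j] <- K[i, j] - s * S[i, j]
    K[j, i] <- K[j, i] - s * S[i, j]
  }
  for (m in str$multi) {
    L <- tryCatch(chol(S[m$idx, m$idx]), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    K[m$idx, m$idx] <- K[m$idx, m$idx] + m$sign * chol2inv(L)
  }
  K
}

# Variance-equality LRT and pooled mean statistic for one labelling.
# Returns c(var_stat, pooled_T2) (NAs when a fit degenerates).
ggm_step_stats <- function(Z, i1, str, estimator) {
  Z1 <- Z[i1, , drop = FALSE]
  Z2 <- Z[!i1, , drop = FALSE]
  n1 <- nrow(Z1); n2 <- nrow(Z2); n <- n1 + n2
  S1 <- estimator(Z1); S2 <- estimator(Z2)
  Sp <- (n1 * S1 + n2 * S2) / n
  d <- colMeans(Z2) - colMeans(Z1)
  a1 <- margin_stats(S1, str)
  a2 <- margin_stats(S2, str)
  ap <- margin_stats(Sp, str, d = d)
  if (is.null(a1) || is.null(a2) || is.null(ap)) return(c(NA_real_, NA_real_))
  c(n * ap$ld - n1 * a1$ld - n2 * a2$ld,
    (n1 * n2 / n) * ap$quad)
}

# Batched evaluation of (var_stat, pooled_T2) over many labellings at
# once. Applicable when every margin has size <= 2, so log-determinants
# and quadratic forms have closed forms that vectorize across
# permutations; the needed covariance entries come from a single
# cross-product of precomputed product columns with the group-indicator
# matrix. Numerically identical to ggm_step_stats on the same labels.
# P: n x B logical matrix of group-1 membership. Returns 2 x B.
ggm_step_stats_batched <- function(Z, P, str, n1, n2,
                                   shrink = FALSE, lambda = NULL) {
  n <- n1 + n2
  p <- ncol(Z)
  storage.mode(P) <- "double"
  B <- ncol(P)
  pi_ <- str$pair_i; pj_ <- str$pair_j
  # product columns: all unordered pairs for the shrinkage intensity,
  # margin pairs only otherwise
  if (shrink && is.null(lambda) && p >= 2) {
    all_pairs <- utils::combn(p, 2)
    ai <- all_pairs[1, ]; aj <- all_pairs[2, ]
  } else {
    ai <- pi_; aj <- pj_
  }
  Z2 <- Z^2
  W11 <- if (length(ai)) Z[, ai, drop = FALSE] * Z[, aj, drop = FALSE] else NULL

  sums <- function(M) if (is.null(M)) NULL else crossprod(M, P) # cols x B
  s1_z <- sums(Z); s1_z2 <- sums(Z2); s1_w <- sums(W11)
  tot_z <- colSums(Z); tot_z2 <- colSums(Z2)
  tot_w <- if (is.null(W11)) NULL else colSums(W11)
  m1 <- s1_z / n1
  m2 <- (tot_z - s1_z) / n2
  v1 <- s1_z2 / n1 - m1^2                      # p x B variances, group 1
  v2 <- (tot_z2 - s1_z2) / n2 - m2^2
  c1 <- c2 <- NULL
  if (length(ai)) {
    c1 <- s1_w / n1 - m1[ai, , drop = FALSE] * m1[aj, , drop = FALSE]
    c2 <- (tot_w - s1_w) / n2 - m2[ai, , drop = FALSE] * m2[aj, , drop = FALSE]
  }

  if (shrink) {
    if (is.null(lambda) && length(ai)) {
      # quartic sums for Var-hat(r_ij), expanded in raw group moments
      W21 <- Z2[, ai, drop = FALSE] * Z[, aj, drop = FALSE]
      W12 <- Z[, ai, drop = FALSE] * Z2[, aj, drop = FALSE]
      W22 <- Z2[, ai, drop = FALSE] * Z2[, aj, drop = FALSE]
      lam_for <- function(sw21, sw12, sw22, s11n, m, v, ng) {
        mi <- m[ai, , drop = FALSE]; mj <- m[aj, , drop = FALSE]
        vi <- pmax(v[ai, , drop = FALSE], .Machine$double.eps)
        vj <- pmax(v[aj, , drop = FALSE], .Machine$double.eps)
        sq <- sw22 - 2 * mj * sw21 - 2 * mi * sw12 +
          mj^2 * (v[ai, , drop = FALSE] + mi^2) * ng +
          mi^2 * (v[aj, , drop = FALSE] + mj^2) * ng +
          4 * mi * mj * s11n - 3 * ng * mi^2 * mj^2
        sw2 <- sq / (vi * vj)
        r <- (s11n / ng - mi * mj) / sqrt(vi * vj)
        varr <- ng / (ng - 1)^3 * (sw2 - ng * r^2)
        lam <- colSums(varr) / pmax(colSums(r^2), .Machine$double.eps)
        pmin(1, pmax(0, lam))
      }
      s1_w21 <- crossprod(W21, P); s1_w12 <- crossprod(W12, P)
      s1_w22 <- crossprod(W22, P)
      lam1 <- lam_for(s1_w21, s1_w12, s1_w22, s1_w, m1, v1, n1)
      lam2 <- lam_for(colSums(W21) - s1_w21, colSums(W12) - s1_w12,
                      colSums(W22) - s1_w22, tot_w - s1_w, m2, v2, n2)
    } else {
      lam1 <- lam2 <- rep(lambda %||% 0, B)
    }
    if (!is.null(c1)) {
      c1 <- c1 * rep(1 - lam1, each = nrow(c1))
      c2 <- c2 * rep(1 - lam2, each = nrow(c2))
    }
  }

  # restrict pair entries to the margin pairs
  if (length(pi_)) {
    sel <- match(paste(pi_, pj_), paste(ai, aj))
    c1m <- c1[sel, , drop = FALSE]
    c2m <- c2[sel, , drop = FALSE]
  } else {
    c1m <- c2m <- matrix(0, 0, B)
  }
  vp <- (n1 * v1 + n2 * v2) / n
  cpm <- (n1 * c1m + n2 * c2m) / n
  d <- m2 - m1

  margin_ld <- function(v, cm) {
    ok <- rep(TRUE, B)
    ld <- numeric(B)
    if (length(str$sing_idx)) {
      vs <- v[str$sing_idx, , drop = FALSE]
      ok <- ok & colSums(vs <= 0) == 0
      ld <- ld + as.numeric(str$sing_sign %*% log(pmax(vs, 1e-300)))
    }
    if (length(pi_)) {
      det2 <- v[pi_, , drop = FALSE] * v[pj_, , drop = FALSE] - cm^2
      ok <- ok & colSums(det2 <= 0) == 0
      ld <- ld + as.numeric(str$pair_sign %*% log(pmax(det2, 1e-300)))
    }
    ld[!ok] <- NA_real_
    ld
  }
  ld1 <- margin_ld(v1, c1m)
  ld2 <- margin_ld(v2, c2m)
  ldp <- margin_ld(vp, cpm)
  quad <- numeric(B)
  if (length(str$sing_idx)) {
    quad <- quad + as.numeric(
      str$sing_sign %*% (d[str$sing_idx, , drop = FALSE]^2 /
                           vp[str$sing_idx, , drop = FALSE]))
  }
  if (length(pi_)) {
    d1 <- d[pi_, , drop = FALSE]; d2 <- d[pj_, , drop = FALSE]
    vi <- vp[pi_, , drop = FALSE]; vj <- vp[pj_, , drop = FALSE]
    det2 <- vi * vj - cpm^2
    quad <- quad + as.numeric(
      str$pair_sign %*% ((d1^2 * vj - 2 * d1 * d2 * cpm + d2^2 * vi) / det2))
  }
  rbind(n * ldp - n1 * ld1 - n2 * ld2,
        (n1 * n2 / n) * quad)
}

# Behrens-Fisher mean statistic d' (Sig1/n1 + Sig2/n2)^-1 d under the
# constrained per-group covariances.
ggm_bf_stat <- function(Z, i1, str, estimator) {
  Z1 <- Z[i1, , drop = FALSE]
  Z2 <- Z[!i1, , drop = FALSE]
  K1 <- ggm_precision(estimator(Z1), str)
  K2 <- ggm_precision(estimator(Z2), str)
  if (is.null(K1) || is.null(K2)) return(NA_real_)
  d <- colMeans(Z2) - colMeans(Z1)
  V <- tryCatch(solve(K1) / nrow(Z1) + solve(K2) / nrow(Z2),
                error = function(e) NULL)
  if (is.null(V)) return(NA_real_)
  tryCatch(drop(crossprod(d, solve(V, d))), error = function(e) NA_real_)
}

ggm_pathway_test <- function(data, graph, cfg, method,
                             estimator, check_clique_size,
                             shrink = FALSE, lambda = NULL) {
  cfg <- as_method_config(cfg)
  measured <- rownames(data$X)
  pg <- intersect(pathway_genes(graph), measured)
  base <- function(...) pathway_result(graph$pathway_id, method,
                                       n_nodes = nrow(graph$nodes),
                                       n_measured = length(pg),
                                       n_deg = NA_integer_, ...)
  if (length(pg) < 2) return(base(status = "not_testable"))
  decomp <- decompose_to_cliques(graph, measured)
  if (check_clique_size && min(data$n1, data$n2) <= decomp$max_clique_size) {
    return(base(status = "not_testable",
                extras = list(max_clique_size = decomp$max_clique_size)))
  }
  Z <- t(data$X[decomp$nodes, , drop = FALSE])
  str <- ggm_structure(decomp)
  i1_obs <- data$y == 1L
  obs <- ggm_step_stats(Z, i1_obs, str, estimator)
  if (anyNA(obs)) {
    return(base(status = "not_testable",
                extras = list(max_clique_size = decomp$max_clique_size)))
  }
  N <- cfg$n_permutations
  perms <- with_seed(cfg$seed, replicate(N, sample(data$y) == 1L))
  if (length(str$multi) == 0 && str$p <= 20) {
    # closed-form margins: evaluate all permutations in one batch
    st <- ggm_step_stats_batched(Z, perms, str, data$n1, data$n2,
                                 shrink = shrink, lambda = lambda)
    nulls <- t(st)
  } else {
    nulls <- matrix(NA_real_, N, 2)
    for (b in seq_len(N)) {
      nulls[b, ] <- ggm_step_stats(Z, perms[, b], str, estimator)
    }
  }
  ok <- !is.na(nulls[, 1])
  var_p <- perm_pvalue(nulls[ok, 1], obs[1])
  equal_cov <- var_p >= cfg$var_alpha
  if (equal_cov) {
    okm <- !is.na(nulls[, 2])
    mean_stat <- obs[2]
    mean_p <- perm_pvalue(nulls[okm, 2], mean_stat)
  } else {
    # unequal covariances: Behrens-Fisher variant, second permutation pass
    mean_stat <- ggm_bf_stat(Z, i1_obs, str, estimator)
    if (is.na(mean_stat)) return(base(status = "degenerate"))
    bf_null <- vapply(seq_len(N), function(b) {
      ggm_bf_stat(Z, perms[, b], str, estimator)
    }, numeric(1))
    mean_p <- perm_pvalue(bf_null[!is.na(bf_null)], mean_stat)
  }
  base(statistic = mean_stat, p_value = mean_p,
       extras = list(var_p = var_p, branch = if (equal_cov) "pooled" else
                       "behrens_fisher",
                     max_clique_size = decomp$max_clique_size))
}

#' Decomposable Gaussian graphical model pathway test (TopologyGSA)
#'
#' The moralized, triangulated pathway graph defines a decomposable
#' Gaussian graphical model; per-group covariances are estimated under the
#' model by the closed-form clique-marginal construction. Step 1 tests
#' covariance equality with a likelihood-ratio statistic; step 2 tests mean
#' equality with a Hotelling-type T-squared using the pooled constrained
#' covariance when step 1 accepts (at `var_alpha`) or a Behrens-Fisher
#' variant otherwise. Both p-values come from sample-label permutation; the
#' pathway p-value is the mean-test p-value, the variance-test p-value is
#' reported in `extras`. The test requires more samples per group than the
#' largest clique has genes; otherwise the pathway is `not_testable`.
#'
#' @inheritParams spia
#' @return A one-row pathway result tibble.
#' @export
topology_gsa <- function(data, graph, cfg = method_config()) {
  ggm_pathway_test(data, graph, cfg, "topologygsa", cov_ml,
                   check_clique_size = TRUE, shrink = FALSE)
}

#' Shrinkage Gaussian graphical model pathway test (Clipper)
#'
#' Same two-step scheme as [topology_gsa()], but clique-marginal
#' covariances come from a shrinkage estimator (correlations shrunk toward
#' zero with a closed-form intensity), so pathways whose largest clique
#' exceeds the group sample size remain testable. The pathway p-value is
#' the sample-permutation mean-test p-value.
#'
#' @inheritParams spia
#' @return A one-row pathway result tibble.
#' @export
clipper <- function(data, graph, cfg = method_config()) {
  cfg <- as_method_config(cfg)
  estimator <- if (!cfg$clipper_shrinkage) {
    cov_ml
  } else {
    function(Z) shrink_cov(Z, lambda = cfg$clipper_lambda)
  }
  ggm_pathway_test(data, graph, cfg, "clipper", estimator,
                   check_clique_size = FALSE,
                   shrink = cfg$clipper_shrinkage,
                   lambda = cfg$clipper_lambda)
}

#' Graph-Fourier Hotelling pathway test (DEGraph)
#'
#' Each weakly connected component of the measured pathway subgraph is
#' analysed in the spectral basis of its unnormalized graph Laplacian
#' L = D - A (symmetrized, unweighted). Samples are projected onto the
#' `k` smoothest eigenvectors (default `k = max(1, ceiling(0.2 m))` for a
#' component of `m` genes) and compared with Hotelling's T-squared,
#' converted to an F p-value on `(k, n1 + n2 - k - 1)` degrees of freedom.
#' The pathway p-value Bonferroni-aggregates the component p-values
#' (minimum times the number of components, capped at 1). Components with
#' singular pooled projected covariance are skipped as degenerate.
#'
#' @inheritParams spia
#' @return A one-row pathway result tibble; per-component p-values in
#'   `extras`.
#' @export
degraph <- function(data, graph, cfg = method_config()) {
  cfg <- as_method_config(cfg)
  measured <- rownames(data$X)
  pg <- intersect(pathway_genes(graph), measured)
  base <- function(...) pathway_result(graph$pathway_id, "degraph",
                                       n_nodes = nrow(graph$nodes),
                                       n_measured = length(pg),
                                       n_deg = NA_integer_, ...)
  if (length(pg) < 1) return(base(status = "not_testable"))
  comps <- measured_components(graph, measured)
  n1 <- data$n1; n2 <- data$n2; n <- n1 + n2
  res <- lapply(comps, function(cp) {
    ids <- sort(cp$nodes$node_id)
    ids <- intersect(ids, measured)
    m <- length(ids)
    Xc <- data$X[ids, , drop = FALSE]
    A <- igraph::as_adjacency_matrix(pathway_igraph(cp, "undirected"),
                                     sparse = FALSE)
    A <- A[ids, ids, drop = FALSE]
    L <- diag(rowSums(A), m) - A
    es <- eigen(L, symmetric = TRUE)
    ord <- order(es$values) # ascending: smoothest first
    k <- max(1L, ceiling(cfg$degraph_k_fraction * m))
    k <- min(k, m)
    U <- es$vectors[, ord[seq_len(k)], drop = FALSE]
    Y <- t(U) %*% Xc # k x n
    if (n - k - 1 <= 0) return(list(p = NA_real_, t2 = NA_real_, k = k))
    Y1 <- Y[, data$y == 1L, drop = FALSE]
    Y2 <- Y[, data$y == 2L, drop = FALSE]
    d <- rowMeans(Y2) - rowMeans(Y1)
    S1 <- tcrossprod(Y1 - rowMeans(Y1)) / (n1 - 1)
    S2 <- tcrossprod(Y2 - rowMeans(Y2)) / (n2 - 1)
    Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n - 2)
    t2 <- tryCatch((n1 * n2 / n) * drop(t(d) %*% solve(Sp, d)),
                   error = function(e) NA_real_)
    if (!is.finite(t2)) return(list(p = NA_real_, t2 = NA_real_, k = k))
    fstat <- (n - k - 1) / ((n - 2) * k) * t2
    list(p = pf(fstat, k, n - k - 1, lower.tail = FALSE), t2 = t2, k = k)
  })
  pvals <- vapply(res, function(r) r$p, numeric(1))
  okc <- !is.na(pvals)
  if (!any(okc)) return(base(status = "not_testable"))
  p_comp <- pvals[okc]
  best <- which.min(p_comp)
  p_path <- min(1, min(p_comp) * length(comps))
  base(statistic = vapply(res[okc], function(r) r$t2, numeric(1))[best],
       p_value = p_path,
       extras = list(component_p = as.list(pvals),
                     component_sizes = vapply(comps, function(cp)
                         nrow(cp$nodes), integer(1)),
                     k = vapply(res, function(r) r$k, numeric(1)),
                     n_components = length(comps)))
}
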