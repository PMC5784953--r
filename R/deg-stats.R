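#' Construct a two-group expression dataset
#'
#' @param X Numeric matrix of log2 expression, rows = genes (unique,
#'   non-empty rownames), columns = samples.
#' @param y Integer vector of group labels in `{1, 2}`, one per column.
#' @return An object of class `expression_dataset` with elements `X`, `y`,
#'   `n1`, `n2`.
#' @export
expression_dataset <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(rownames(X)) || anyDuplicated(rownames(X))) {
    dup <- unique(rownames(X)[duplicated(rownames(X))])
    abort(paste0("gene ids must be unique and non-empty",
                 if (length(dup)) paste0("; duplicated: ",
                                         paste(head(dup, 5), collapse = ", "))))
  }
  if (anyNA(X)) abort("expression matrix contains missing values")
  y <- as.integer(y)
  if (length(y) != ncol(X)) abort("one group label per sample is required")
  if (!all(y %in% c(1L, 2L))) abort("group labels must be 1 or 2")
  structure(list(X = X, y = y, n1 = sum(y == 1L), n2 = sum(y == 2L)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (groups %d/%d)\n",
              nrow(x$X), ncol(x$X), x$n1, x$n2))
  invisible(x)
}

#' Per-gene moderated t-test
#'
#' Two-sample differential expression with empirical-Bayes variance
#' moderation. For each gene the pooled variance \eqn{s_g^2} (on
#' \eqn{d_g = n_1 + n_2 - 2} degrees of freedom) is shrunk towards a prior
#' \eqn{s_0^2} fitted together with its degrees of freedom \eqn{d_0} by
#' moment matching on \eqn{\log s_g^2} (closed-form trigamma inversion with
#' a numeric fallback):
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
#'       \tilde t_g = \frac{\mathrm{logFC}_g}{\tilde s_g\sqrt{1/n_1 + 1/n_2}}}
#' with two-sided p-values from a t-distribution on \eqn{d_0 + d_g} degrees
#' of freedom. `logFC` is group 2 mean minus group 1 mean (log2 units).
#' Genes constant across all samples are flagged and assigned
#' `logFC = 0, p = 1`.
#'
#' @param data An [expression_dataset()] with at least two samples per group.
#' @param d0 Optional override of the prior degrees of freedom: `0` recovers
#'   the ordinary pooled two-sample t-test, `Inf` fully trusts the prior
#'   variance. Default `NULL` fits d0 from the data.
#' @return An object of class `deg_result`: a tibble with columns `gene`,
#'   `logfc`, `t`, `p_value`, `flat`, plus attributes `d0`, `s0sq`, `df_total`.
#' @export
moderated_t <- function(data, d0 = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  if (data$n1 < 2 || data$n2 < 2) abort("both groups need at least 2 samples")
  X1 <- data$X[, data$y == 1L, drop = FALSE]
  X2 <- data$X[, data$y == 2L, drop = FALSE]
  n1 <- data$n1; n2 <- data$n2
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  logfc <- m2 - m1
  dg <- n1 + n2 - 2
  ssq <- (rowSums((X1 - m1)^2) + rowSums((X2 - m2)^2)) / dg
  flat <- ssq <= 0 & abs(logfc) < .Machine$double.eps^0.5

  fit <- if (is.null(d0)) {
    fit_variance_prior(ssq[ssq > 0], dg)
  } else {
    list(d0 = d0,
         s0sq = if (d0 > 0) fit_variance_prior(ssq[ssq > 0], dg)$s0sq
                else NA_real_)
  }
  d0 <- fit$d0; s0sq <- fit$s0sq

  if (is.infinite(d0)) {
    stilde <- rep(s0sq, length(ssq))
    df_tot <- Inf
  } else if (d0 <= 0) {
    stilde <- ssq
    df_tot <- dg
  } else {
    stilde <- (d0 * s0sq + dg * ssq) / (d0 + dg)
    df_tot <- d0 + dg
  }
  se <- sqrt(stilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, ifelse(abs(logfc) > 0, sign(logfc) * Inf, 0))
  p <- 2 * pt(-abs(tstat), df = df_tot)
  p[flat] <- 1
  tstat[flat] <- 0
  out <- tibble(gene = rownames(data$X), logfc = unname(logfc),
                t = unname(tstat), p_value = unname(p), flat = unname(flat))
  structure(out, class = c("deg_result", class(out)),
            d0 = d0, s0sq = s0sq, df_total = df_tot)
}

# Moment matching of a scaled inverse-chi-square prior on the log pooled
# variances: e_g = log s_g^2 - digamma(dg/2) + log(dg/2) has mean
# log s0^2 + digamma(d0/2) - log(d0/2) and variance trigamma(d0/2) +
# trigamma(dg/2); invert the trigamma by Newton steps.
fit_variance_prior <- function(ssq, dg) {
  if (length(ssq) < 2) return(list(d0 = Inf, s0sq = mean(ssq)))
  e <- log(ssq) - digamma(dg / 2) + log(dg / 2)
  ev <- mean(e)
  vv <- var(e) * (length(e) - 1) / length(e) - trigamma(dg / 2)
  if (!is.finite(vv) || vv <= 0) {
    return(list(d0 = Inf, s0sq = exp(ev)))
  }
  half_d0 <- trigamma_inverse(vv)
  d0 <- 2 * half_d0
  s0sq <- exp(ev + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0sq = s0sq)
}

# Solve trigamma(y) = x for y > 0 (Newton on log-scale; monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Call differentially expressed genes
#'
#' Strict-inequality thresholding of the moderated-t p-values: the DEG set
#' is `{g : p_g < theta}`. No multiple-testing correction is applied.
#'
#' @param result A [moderated_t()] result.
#' @param theta Significance level in (0, 1); default 0.05.
#' @return Character vector of DEG gene ids, with attribute `theta`.
#' @export
call_degs <- function(result, theta = 0.05) {
  stopifnot(theta > 0, theta < 1)
  structure(result$gene[result$p_value < theta], theta = theta)
}
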