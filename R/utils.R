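#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median pf pt phyper var cor sd rnorm runif setNames
#' @importFrom utils combn head
NULL

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Permutation p-value, (1 + exceedances) / (1 + N); never exactly zero.
perm_pvalue <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
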