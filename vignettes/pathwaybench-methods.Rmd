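---
title: "Topology-based pathway analysis: models, conventions and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based pathway analysis: models, conventions and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaybench)
```

## The problem

Given a log2 gene expression matrix with two sample groups and a collection
of pathways whose interaction structure is known a priori, topology-based
pathway analysis asks which pathways are differentially expressed between
the groups — and, unlike plain enrichment, it lets the position of the
deregulated genes in the interaction network influence the answer. Methods
in this family differ along three axes that determine their behaviour far
more than implementation detail does: the null hypothesis (*competitive*,
comparing the pathway against the rest of the measured genome, vs
*self-contained*, testing the pathway's genes alone), whether a hard list of
differentially expressed genes (DEGs) is formed first (*ORA*) or all
gene-level statistics are used (*FCS*), and whether the pathway is scored
gene-by-gene (*univariable*) or as a joint multivariate observation
(*multivariable*).

`pathwaybench` implements seven representative methods on one shared
pathway-graph data model, together with a synthetic data generator and a
suite of controlled experiments (type-I calibration, sample/pathway-size
sensitivity, single-gene / gene-set / motif influence profiling, topology
ablation, pre-processing contrasts) designed to expose those axes.

## The data model

A pathway arrives as a `raw_pathway`: gene nodes, multi-subunit `complex`
nodes, `family` nodes (interchangeable members), non-gene `compound` nodes
(metabolites), and typed, optionally directed edges. `preprocess_topology()`
converts it to a gene-level `pathway_graph` under one of four conventions:

* **`gpt`** (the default, expanded convention): complexes are expanded to
  their member genes joined pairwise by undirected neutral binding edges;
  family members each inherit every family edge; compound nodes are removed
  and their incident interactions bridged (`A -> compound -> B` becomes
  `A -> B`, inheriting the signed hop's type, or a neutral `compound` edge
  if neither hop carries a sign).
* **`mspt_combined`**: complexes and families stay as single combined nodes
  carrying all member gene ids (the original convention of the
  downstream-DEG and centrality methods).
* **`mspt_degraph`**: expanded, but without the within-complex binding
  edges.
* **`mspt_spia`**: expanded, but compound-mediated interactions are dropped
  rather than bridged, so perturbations do not travel through metabolites.

Edge types map to signs through a fixed vocabulary
(`interaction_signs()`): activation/expression/phosphorylation are +1,
inhibition/repression/dephosphorylation are −1, and
binding/association/indirect/compound are neutral. The vocabulary is the
package's own choice — pathway databases do not agree on one — and it is
deliberately minimal; unknown types are rejected rather than guessed.

Two further conventions apply everywhere. All methods operate on the
subgraph induced by the measured genes (no contraction of edges through
unmeasured nodes), and pathways are filtered to at most 150 genes with at
least two measured genes. `strip_interactions()` produces the edgeless
(`NOGPT`) view used by the ablation experiment.

## Gene-level statistics

The ORA methods need per-gene statistics. `moderated_t()` implements the
standard empirical-Bayes moderated t-test: per-gene pooled variances
$s_g^2$ on $d_g = n_1 + n_2 - 2$ degrees of freedom are shrunk towards a
prior $s_0^2$ whose weight $d_0$ is fitted by moment matching on
$\log s_g^2$ (closed-form trigamma inversion, Newton fallback):

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
\tilde t_g = \frac{\bar x_{g2} - \bar x_{g1}}
{\tilde s_g \sqrt{1/n_1 + 1/n_2}} \sim t_{d_0 + d_g}.$$

The implementation is the package's own (the `d0` argument can force the
ordinary pooled t-test, `d0 = 0`, or the common-variance limit,
`d0 = Inf`, both of which the tests exercise); the independent limma
implementation serves as an oracle in the test suite. DEG calling uses the
raw p-value with a strict threshold (`p < theta`, default 0.05) and no
multiple-testing correction — deliberately, because the benchmarks study
the methods under their conventional operating settings, where raw
thresholds are applied to genes and pathways alike.

## The seven pathway tests

**SPIA-style perturbation propagation** (`spia`, competitive ORA). DEG log
fold changes are propagated through the signed network: with
$B_{ij} = \beta_{j\to i} / N_{ds}(j)$ (each gene divides its signal over
its signed out-edges), the perturbation factors solve $(I - B)PF = \Delta E$
and the pathway statistic is $t_A = \sum_i (PF_i - \Delta E_i)$.
Significance combines a hypergeometric DEG over-representation p-value
$p_{NDE}$ with a bootstrap p-value $p_{PERT}$ (observed DEG log fold
changes placed on random pathway genes) as
$p_G = c - c\log c$, $c = p_{NDE} \cdot p_{PERT}$. When $(I - B)$ is
singular (e.g. an unbroken feedback loop of signed edges) the pathway is
reported `degenerate` rather than silently damped; with no DEGs or no
signed edges, $p_G$ reduces to $p_{NDE}$.

The tail convention for $p_{PERT}$ deserves a note. The package's default
compares magnitudes, $P(|t_A^{null}| \ge |t_A^{obs}|)$. A two-sided test
centred on the null median is also available (`pert_p = "median"`), but on
symmetric topologies it makes upstream and downstream genes exactly equally
influential — the null placements mirror the observed one — which
contradicts the method's characteristic root-node sensitivity (genes
without incoming interactions and with many downstream targets are the
influential ones, which is also what the influence experiments here show).
The magnitude tail preserves that behaviour and remains sign-safe for
inhibition-dominated pathways.

**PRS-style downstream-DEG weighting** (`prs`, competitive ORA). Each DEG
node contributes $|logFC| \cdot (1 + \#\{\text{distinct DEG nodes reachable
downstream}\})$; the score is summed over DEG nodes and referred to a null
in which DEG statuses (with their log fold changes) are permuted over all
measured genes. The score normalized by the null mean is kept in `extras`;
inference uses the permutation rank.

**CePa-style centrality weighting** (`cepa`, competitive ORA). The DEG
indicator is summed under six node weights — in/out degree, betweenness,
in/out reach (longest finite shortest-path distance into/out of a node),
and equal weight — each with its own competitive permutation p-value. The
pathway p-value is the *uncorrected minimum* of the six. This choice
reproduces the anti-conservative behaviour of the published approach; the
type-I-error experiment measures exactly this inflation, so the package
does not correct it. Per-centrality p-values are reported in `extras`.

**TAPPA-style connectivity index** (`tappa`, FCS). Per-gene z-scores
(standardized across all samples) enter a quadratic form over the
symmetrized adjacency with self-loops,
$PCI_s = \sum_{i \le j, A^*_{ij}=1} \mathrm{sign}(z_{is})
\mathrm{sign}(z_{js}) \sqrt{|z_{is}||z_{js}|} / |V|$,
giving one pathway-expression value per sample; groups are compared with a
two-sided Mann–Whitney test (exact for group sizes up to 20, tie-corrected
normal approximation beyond). On an edgeless pathway the index collapses to
the mean absolute z-score. The per-gene z-scoring is the package's
normalization choice (the original array-level normalization is not fully
specified in the sources this design follows) and is isolated behind
`tappa_pci()` so it can be audited or replaced.

**TopologyGSA-style decomposable GGM test** (`topologygsa`, self-contained
FCS). The pathway DAG (directed cycles broken deterministically first) is
moralized and triangulated with deterministic minimum-fill; per-group
covariances are estimated under the resulting decomposable Gaussian
graphical model by the closed-form clique-marginal construction
$K = \sum_C [(S_{CC})^{-1}]^0 - \sum_S [(S_{SS})^{-1}]^0$. Step 1 tests
covariance equality by likelihood ratio; step 2 tests mean equality with a
Hotelling-type $T^2$ using the pooled constrained covariance if step 1
accepts (at 0.05), or a Behrens–Fisher form otherwise. Both p-values come
from sample-label permutation; the mean-test p-value is the pathway
p-value. The method requires more samples per group than the largest clique
has genes, and is reported `not_testable` otherwise — this failure mode is
itself one of the benchmarked behaviours.

**Clipper-style shrinkage GGM test** (`clipper`). The same two-step scheme
with a James–Stein-type shrinkage covariance inside the clique marginals
(correlations shrunk towards zero with the closed-form intensity
$\lambda^* = \sum_{i \ne j}\widehat{Var}(r_{ij}) / \sum_{i \ne j} r_{ij}^2$,
clipped to $[0,1]$), so cliques larger than the group size stay testable.
With $\lambda = 0$ it reproduces the ML test exactly, which the test suite
asserts.

**DEGraph-style graph-Fourier test** (`degraph`, self-contained FCS). Each
weakly connected measured component is projected onto the $k$ smoothest
eigenvectors of its unnormalized Laplacian $L = D - A$ (default
$k = \max(1, \lceil 0.2\,m\rceil)$ for $m$ genes — an energy-style
truncation keeping the low-frequency fifth of the spectrum), followed by
Hotelling's $T^2$ with an F-transform p-value on $(k, n_1 + n_2 - k - 1)$
degrees of freedom. Component p-values are Bonferroni-aggregated (minimum
times the number of components, capped at 1). With $k = m$ the projection
is an orthogonal rotation and the classical Hotelling test is recovered to
machine precision; singleton components reduce to per-gene t-tests.

### Shared numerical conventions

* Permutation p-values are always $(1 + \#\{null \ge obs\})/(1 + N)$,
  bounded away from zero; $N$ defaults to 1000 (`method_config()`).
* The DEP flag is `p < alpha` with `alpha = 0.05`.
* Triangulation uses deterministic min-fill with lexicographic tie-breaks;
  cycle-breaking removes the lexicographically-last edge of each directed
  cycle. Any triangulation would be statistically valid — determinism is
  for reproducibility.
* The variance-test branch threshold of the two-step tests is fixed at
  0.05 (`var_alpha`).
* Degenerate inputs are reported as statuses (`not_testable`,
  `degenerate`) rather than coerced into p-values.

## The synthetic generator

`generate_base_dataset()` emulates a large two-group breast-tumour
microarray matrix under the global null: per-gene means
$\sim N(7, 2^2)$ (log2 scale) and SDs $\sim |N(0.5, 0.25^2)| + 0.1$,
compound-symmetric correlation blocks of 20 genes at $\rho = 0.2$
(co-regulation), and an unbalanced 120/60 design mimicking an estrogen
receptor split. The 2000-gene default universe is sized for desk-scale
benchmarking; everything is configurable and every generator is a pure
function of (config, seed). Group effects are injected afterwards with
`induce_shift()` (exact additive log2 shifts on chosen genes in one
group), `null_relabel()` manufactures null hypotheses, and `subsample()`
reduces sample size preserving group proportions.

What the generator does *not* emulate: heavy-tailed and platform-specific
noise, probe-level artefacts, correlated DEG blocks aligned with pathway
boundaries, batch effects, and missing values. Passing calibration and
sensitivity benchmarks on this generator therefore demonstrates the
methods' statistical behaviour under clean Gaussian co-regulated data, not
their robustness to real microarray pathologies.

`toy_pathway_suite()` provides eight deterministic fixtures (chain, star,
directed triangle, co-parent DAG, complex/family/compound-node pathways, a
30-gene random DAG) spanning everything the pre-processing must handle;
`benchmark_pathway_suite()` adds twelve seeded random DAGs of 10–60 genes
for a 20-pathway collection with a realistic size spread.

## The experiments

`ex1_sample_size()` … `ex8_preprocessing()` wrap the controlled benchmarks:
subsampling sweeps, type-I error under null relabeling, single-gene /
gene-set / motif overexpression influence profiles, target-pathway ranking
(dense ranks: ties share a rank, ranks increment by one between distinct
p-values), topology ablation and pre-processing contrasts. All return a
`pb_report` (long tidy rows + summary tables; `tidy()`, `glance()`,
`autoplot()`), and all are pure functions of (inputs, config, seed).
Influence is the proportion of DEP calls pooled uniformly over all
increments and replicates, binned into five categories (very low
$[0, 0.2)$ … very high $[0.8, 1]$). Medians use the lower-interpolation
convention. Replicate base datasets are shared across genes and increments
at matched (replicate, shift) — a paired design that removes dataset noise
from within-pathway influence comparisons.

Two experiment-design decisions worth making explicit: the type-I-error
experiment realizes its null hypotheses as (relabelings × pathways) rather
than a fixed breakdown, trimmed to the requested count; and the
single-gene influence experiment pools increments uniformly (not weighted
by replicate counts) when summarizing a gene's influence.

## Problem sizes used by the shipped checks

The package's test suite and `scripts/acceptance.R` run everything at desk
scale, chosen so the full suite completes on a single CPU in well under
half an hour while keeping Monte-Carlo error small relative to the effects
being asserted: null calibration uses 500 tests per method (20 pathways ×
25 relabelings, 200 permutations, 60/30 samples, 2000 genes); influence
monotonicity uses 20 replicate datasets over the 0.1–2.0 shift grid;
oracle comparisons (propagation fixed points, clique-marginal
reproduction, spectral-limit Hotelling) use dozens of random instances at
tolerances of 1e-8 or tighter. These sizes are the package's own choices
and are configurable in every experiment.

## Known limitations

* Pre-processing reconstructs the conventions from their published
  descriptions; the exact bridging rules of database-specific converters
  (multi-step compound chains, type inheritance) vary across releases, and
  the implementation documents its own rule rather than tracking any one
  release.
* The connectivity-index normalization and the perturbation-bootstrap tail
  convention are reconstruction choices (both configurable, both flagged
  above).
* Combined-node graphs summarize a node by its most extreme member gene
  (ORA methods) or the member mean (connectivity index); other
  summaries are defensible.
* The motif isomorphism classes ignore edge signs and types; a
  sign-sensitive classification would split some classes.
* Multi-group designs, continuous phenotypes, sub-path analyses and
  RNA-seq count models are out of scope.
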