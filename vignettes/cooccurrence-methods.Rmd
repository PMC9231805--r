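---
title: "Methods: SparCC networks, their analyses, and the choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SparCC networks, their analyses, and the choices behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the statistics it implements:
the model assumptions, the tunable parameters and their defaults, what the
synthetic benchmark does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

```{r setup, message = FALSE}
library(sparccnet)
```

## Why basis correlations

Amplicon count tables are compositional: each sample's counts sum to the
sequencing depth, so the observed fractions carry only relative
information. Pearson or Spearman correlations between fractions are biased
by this closure — with few dominant taxa the bias can manufacture strong
spurious negatives. SparCC sidesteps the closure by working with
log-ratio variances, which are invariant to per-sample scaling:

$$t_{ij} = \mathrm{Var}\left[\log(x_i/x_j)\right]
         = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}.$$

The $D(D-1)/2$ observed $t_{ij}$ over-determine the $D$ basis variances
$\omega_i$ once one assumes the correlation matrix is *sparse* (most
$\rho_{ij}\approx 0$): dropping the correlation terms row-wise yields the
linear system

$$\left[(D-2)\,I + J\right]\,\omega = t\,\mathbf{1},$$

with $J$ the all-ones matrix, which `basis_correlations()` solves exactly
(no iterative approximation), and $\rho$ follows from the displayed
identity, clamped to $[-1, 1]$.

Assumptions worth keeping in mind:

* **Sparsity.** A community where most taxa are strongly coupled violates
  the approximation; the exclusion mechanism (below) mitigates moderate
  violations, it does not repair dense dependence.
* **At least 3 taxa** are needed for identifiability; estimates sharpen
  quickly with the number of taxa because each $\omega_i$ borrows from all
  pairs.
* **Non-negativity of the solved system is not guaranteed.** A solved
  $\omega_i \le 0$ (possible at small $D$ or pathological $t$) flags the
  taxon as degenerate; its correlations are reported as 0 with a warning
  rather than producing complex numbers. The closed-form three-taxon case
  with $t = \{0.5, 0.5, 2\}$ exercises this path in the tests.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_iterations` | 50 | outer Dirichlet-resampling iterations; the estimate is the entrywise median across them |
| `exclusion_threshold` | 0.10 | keep excluding the most correlated pair while its \|rho\| exceeds this |
| `exclusion_max` | 10 | maximum excluded pairs per pass |
| `n_permutations` | 100 | Monte-Carlo permutations for p-values (50 is a common quick-mode value) |
| `perm_iterations` | 5 | outer iterations inside each permutation run |
| `scratch_path` | unset | HDF5 file for disk-backed per-iteration storage |

The defaults of 50 iterations, exclusion number 10 and threshold 0.10 are
the settings at which edge counts stabilise in parameter sweeps on real
communities, and we keep them as the package defaults. Exclusion
tie-breaks take the lexicographically smallest (row, column) pair so runs
are deterministic; one pair is excluded per round with the system
re-solved in between, and "exclusion number" counts excluded *pairs*.

**Zeros.** Fractions are drawn per sample from
$\mathrm{Dirichlet}(\text{counts}+1)$ — the Bayesian posterior with a
uniform prior — which guarantees strict positivity for the log-ratios and
doubles as the resampling device across outer iterations. With
`resample = FALSE` the table must already be zero-free; all iterations
would then be identical, so a single pass is run. This is the
configuration in which the estimator is checked against the independent
closed-form $D = 3$ solution to $10^{-10}$.

**p-values.** One-sided by default:
$p_{ij} = (1 + \#\{\rho^{perm}_{ij} \ge \rho^{obs}_{ij}\})/(n+1)$ for
non-negative observations, mirrored for negatives; two-sided uses
$|\rho|$. The add-one estimator bounds p away from zero at $1/(n+1)$.
Permutation runs reuse the fit's exclusion settings but default to 5 outer
iterations: the null has no structure for the resampling median to
stabilise, and the reduction keeps 100 permutations affordable; the
setting is exposed (`perm_iterations`) for users who want full-depth
permutations.

**Disk-backed runs.** With `scratch_path` set, each iteration's
correlation matrix goes to `/iter_<k>/rho` in an HDF5 file and the median
is aggregated in row chunks (about 4·10⁶ numbers resident at a time), so
the correlation stage's memory no longer scales with
`n_iterations × n_taxa²`. In-memory and disk-backed runs agree to
`1e-12` by test.

## The synthetic benchmark

`generate_community()` draws, per sample, a multivariate normal on the log
scale with covariance
$\mathrm{diag}(\sigma)\,B\,\mathrm{diag}(\sigma)$ for a planted basis
correlation matrix $B$, exponentiates, normalises, and draws a multinomial
of `depth` reads — i.e. log-normal absolute abundances observed through
multinomial sequencing. Defaults (`log_mean = 0`, `log_sd = 1`,
`depth = 10000`, 50 taxa × 200 samples) follow the classical validation
design for compositional correlation estimators. `generate_sparse_basis()`
plants `n_strong` pairs at ±`strength`; while `n_strong ≤ n_taxa/2` the
pairs are taxon-disjoint, making the matrix block-diagonal and exactly
PSD, so the planted values survive unchanged — overlapping ±0.8 pairs are
mutually inconsistent and would be shrunk by the eigenvalue-clipping PSD
repair (`nearest_psd_correlation()`), which remains the fallback for
denser designs.

On this design the package's median overall RMSE between estimated and
planted correlations is about 0.07 (five seeds; `validate_sparcc()`
recomputes it, and `scripts/acceptance.R` reports it).

What the generator does **not** emulate: overdispersion beyond the
multinomial, taxon-specific sequencing biases, structural zeros (taxa
absent from niches rather than undersampled), longitudinal dependence
between samples, and phylogenetic correlation among taxa. Tests passing on
this benchmark show the estimator and analyses are implemented correctly
and calibrated under the stated model — not that real mats or ferments
meet the model.

## Network construction

The paperwork between a correlation matrix and a graph is explicit in
`build_network()`: keep pairs with `p < alpha` (default when p-values
exist), or with `|rho| >= min_abs_corr`, or all pairs. The default
magnitude threshold is 0 — the complete weighted graph — because any
sharper default silently destroys information; thresholds belong in the
user's hands. Edges carry `raw_weight` $\in [-1,1]$ and
`norm_weight = (raw+1)/2` $\in [0,1]$; the affine map preserves order and
sign (`raw > 0 ⇔ norm > 0.5`). Topological metrics (paths, clustering,
communities, centralities) run on the *unweighted* edge set; raw signs
feed only the positive:negative ratio and the triad census. This keeps
path lengths and diameters in units of hops, which is how the
corresponding ecological literature reports them.

## Topology, nulls and CCDF

`summarize_topology()` reports density, mean/SD degree, the
positive:negative edge ratio (∞ when no negatives — a marker, not an
error), average local clustering (nodes of degree < 2 count 0, the
convention of the reference network stack), average shortest path and
diameter on the giant component when disconnected (flagged
`giant_component_only`), greedy-modularity modularity, and the small-world
index

$$SW = \frac{cc / cc_{rand}}{l / l_{rand}},$$

averaged over `sw_replicates` Erdős–Rényi graphs matched on nodes and
edges. On matched random graphs SW concentrates near 1 (tested to ±0.25);
values above 1 indicate small-world character. Note that greedy modularity
is a heuristic whose tie-breaking follows vertex order, so the reported
modularity can shift by a few hundredths under relabeling; the metric
definitions themselves are label-invariant.

`null_distributions()` generates matched random (Erdős–Rényi `gnm`),
small-world (Watts–Strogatz, ring degree = round(avg degree) forced even
by the lattice construction, rewiring 0.1) and scale-free
(Barabási–Albert, attachment m = round(avg degree / 2)) replicates with
symmetric uniform [-1, 1] weights, and `null_quantiles()` locates the
observed metrics within each null. Degree-distribution comparison uses the
binned PDF (`frequency/total`), its cumulative sum, and
`CCDF = 1 − CDF`, with unit-width integer bins by default (exact for
degrees); `compare_ccdf()` evaluates observed and one matched replicate
per topology on shared bins for log-log plotting.

## Structural balance

`triad_census_signed()` classifies each triangle by the product of its
edge signs: (+,+,+) and (+,−,−) balanced, (+,+,−) and (−,−,−) imbalanced.
The default enumerates **every** 3-clique exactly once (via the graph's
triangle lister, verified against brute-force triple enumeration on random
graphs). A `cycle_basis` mode restricts the census to length-3 cycles of a
fundamental cycle basis — a procedure some published pipelines use — but a
cycle basis does not contain every triangle, so that mode undercounts; it
exists only to reproduce and study that behaviour, and the package default
is the full enumeration. Exact-zero weights are not edges; they are
dropped with a warning before the census.

## Percolation

`percolate()` removes `ceil(step_fraction × n)` nodes per step,
cumulatively and without replacement, until the network is empty — the
cumulative reading of "iterative removal", which makes the trace a single
coherent degradation trajectory (independent resamples per step are
recoverable by calling with different seeds). Centrality-targeted
strategies order nodes by centrality computed **once** on the intact
network; static ordering is the default because it is the common
convention when no recomputation is specified, and an `adaptive` flag
recomputes per step for users who want the stronger attack. Louvain runs
at every step under a step-derived seed so traces are bit-reproducible.
`robustness_report()` condenses a trace into per-metric areas under the
trajectory plus the removal fraction at which the giant component first
drops below half.

## Communities and centralities

Louvain runs on the binary edge set by default — the analyses upstream
threshold edges rather than weight them — with a `weighted` flag for the
[0, 1] weights. HDBSCAN noise (label −1) becomes its own `"noise"` group
and single-node groups are flagged noise-like. Phylum is the second
`";"`-field of the taxonomy string, with an `"NA"` bucket for unassigned
or short taxonomies. Closeness uses the component-size scaling
$\frac{r-1}{n-1}\cdot\frac{r-1}{\sum d}$ on disconnected graphs (matching
the reference network stack), PageRank uses damping 0.85 with undirected
edges as reciprocal links, and rank columns break ties by taxon ID for
determinism.

## Embedding and clustering taxa

`embed_cluster()` treats taxa as points (samples as features), converts
counts to per-sample relative abundances (Bray–Curtis presupposes
compositions; a `relative = FALSE` escape hatch exists), computes the
input dissimilarity (Bray–Curtis default; Euclidean, Manhattan and
Hellinger available), embeds with UMAP (15 neighbours, min_dist 0.1, 2
components) and clusters the coordinates with HDBSCAN (Bray–Curtis on the
embedding, min cluster size 15, min samples 5). The low-dimensional layout
is optimised under Euclidean output geometry — the standard choice, and
the only one the layout optimiser supports; in practice the clustering
runs on its own metric over the coordinates, so the output geometry is not
load-bearing. Outliers are flagged where the GLOSH score exceeds its
empirical 0.9 quantile.

HDBSCAN is implemented in the package (no R implementation with GLOSH was
available to build on): core distances use the `min_samples`-th nearest
neighbour including the point itself; single linkage on
mutual-reachability distances gives the hierarchy; branches smaller than
`min_cluster_size` fall out of their cluster at the split's density level
λ = 1/distance; clusters are selected by excess-of-mass stability with
the root never selectable; GLOSH is
$(\lambda_{death}(c) - \lambda(p)) / \lambda_{death}(c)$ for the last
cluster $c$ containing $p$. Duplicate points merge at distance 0 (λ = ∞);
λ values are capped at the largest finite level so stabilities stay
finite. The implementation reproduces the labels of the reference
scikit-learn implementation exactly on separable fixtures (tested), and
recovers planted abundance blocks with adjusted Rand ≥ 0.9 across seeds.

A note on expectations: density clustering needs tens of points per
expected group; below ~50 taxa, interpret clusters cautiously and shrink
`min_cluster_size` deliberately.

## Problem sizes and numerical choices

The test suite exercises the full validation design (50 × 200, five
seeds — a few seconds per fit), 100-graph census comparisons at up to 50
nodes, 200-node null-model checks with 20 replicates, and 80–100-node
percolation sweeps over 10 seeds; these sizes give stable test statistics
while keeping the whole suite under a minute. Other numerics: variation
matrices are computed from one covariance call (not a pairwise loop) and
clipped at 0; correlation matrices are symmetrised and clamped after the
median aggregation; PSD repair is eigenvalue clipping followed by
rescaling to unit diagonal; quantile thresholds use the empirical (type-7)
quantile.

## Known limitations

* SparCC assumes sparsity of the true correlation structure; densely
  coupled communities need different machinery (e.g. latent-factor
  models).
* P-values are not adjusted for multiplicity; with thousands of pairs,
  apply `p.adjust()` to `tidy(fit)$p.value` before thresholding at
  conventional levels.
* The Watts–Strogatz and Barabási–Albert matchings hit the target density
  only up to rounding of the ring/attachment degree (within ~10%, warned
  otherwise); exact density matching is only possible for the
  Erdős–Rényi null.
* Embedding coordinates are reproducible for a fixed seed on one machine,
  but not guaranteed to be bit-identical across BLAS builds or platforms.
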