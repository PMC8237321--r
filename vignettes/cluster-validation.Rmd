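---
title: "Validating clusterings of weighted networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating clusterings of weighted networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustvalid)
library(igraph)
```

Community-detection algorithms return a partition for *any* input graph,
including graphs with no community structure at all.  clustvalid asks two
questions about a partition of an undirected weighted network: is it
**significant** — are its clusters denser inside and sparser outside than
chance would produce under a null model that preserves the network's basic
constraints — and is it **stable** — does it survive resampling of the
vertices and small perturbations of the edge weights?  This vignette
documents the models behind both answers, the tunable parameters and the
defaults chosen for them, the numerical decisions, and what the built-in
benchmark does and does not establish.

## Graphs, partitions and notation

Graphs are `igraph` objects: undirected, simple, with strictly positive
edge weights $w_{uv}$ (weight zero is the same as no edge) and an optional
declared upper bound on the weights (graph attribute `upper_bound`),
natural for correlation-derived networks where $w_{uv} \le 1$.  For a
cluster $S$ we write $n_S$ for its vertex count, $\tilde m_S$ for its
internal weight, $\tilde c_S$ for the weight crossing its boundary, and
$\tilde d(u)$ for the weighted degree (strength) of a vertex; $\tilde m$
is the total graph weight.  `cluster_aggregates()` computes all of these
in one pass over the edge list, so every score below costs $O(m)$.

## Community scoring functions

`score_specs()` lists the eleven scores.  The cluster-level ones follow
the standard internal/external-connectivity catalogue, extended to
weights by replacing edge counts with weight sums: internal density
$\tilde m_S / \binom{n_S}{2}$, edges inside, average degree, expansion
$\tilde c_S / n_S$, cut ratio, conductance
$\tilde c_S / (2\tilde m_S + \tilde c_S)$, normalized cut, and the
maximum and average out-degree fractions.  On a 0/1-weight graph each
weighted score equals its unweighted counterpart exactly — the test suite
asserts this equivalence on random binary graphs.

Two properties organise the catalogue:

* **Direction** — for internal-connectivity scores higher is better; for
  external ones lower is better.  Significance percentiles are read
  accordingly.
* **Scaling class** — multiplying all weights by $\varphi > 0$ leaves
  conductance, normalized cut, the two ODFs, the clustering coefficient
  and modularity unchanged, while the other five scale linearly.  The
  invariant scores are the ones that compare networks of different
  overall weight meaningfully, and the property is tested to $10^{-9}$
  relative tolerance.

Partition-level values are the unweighted mean of the per-cluster values
over the clusters where the score is defined, with the number of
undefined (NaN) clusters reported alongside.  The plain mean is a
deliberate, isolated choice (`score_partition()`): nothing downstream
depends on it, and a size-weighted mean could be substituted in one
place.  Undefined cases are returned as NaN rather than forced to a
number: internal density of a singleton, conductance and normalized cut
of a cluster with no incident weight.

**Modularity** is computed from the same aggregates as
$Q = \sum_S [\tilde m_S/\tilde m - (D_S/2\tilde m)^2]$ with $D_S$ the
total strength of $S$; the test suite cross-checks it against igraph's
implementation and its invariance under uniform scaling.

**Weighted clustering coefficient.**  Among the candidate definitions,
the per-vertex normalisation used by Barrat's coefficient is degenerate
exactly where weighted information matters most: on a complete weighted
graph it is identically 1 whatever the weights
(`barrat_local_coefficient()` is included as that comparison baseline).
The coefficient used for scoring instead thresholds the graph: for
$t \ge 0$ let $C_t$ be the transitivity of the binary graph keeping
edges with $w \ge t$, and define
$\tilde C = \frac{1}{\bar w}\int_0^{\bar w} C_t\,dt$, with $\bar w$ the
declared upper bound or else the maximum weight.  $C_t$ is a step
function whose critical points are the minimum edge weights of the
connected triplets, so the integral is computed exactly as a finite sum
over the sorted distinct thresholds, in $O(m + \Gamma\log\Gamma)$ for
$\Gamma$ triplets.  Two conventions close gaps the integral formula
leaves open: segments where no connected triplet survives contribute 0
(keeping $\tilde C \in [0,1]$), and thresholds start just above 0
because zero-weight pairs are never edges.  Correctness is anchored to a
brute-force Riemann sum of $C_t$ over $10^4$ grid points with igraph's
transitivity as the inner oracle.

## The switching null model

Significance needs a null: a graph that shares the original's weighted
degree sequence but is otherwise unstructured.  Each elementary step
draws two distinct edges $(A,C)$ and $(B,D)$ uniformly without
replacement, randomises the endpoint roles with fair coins, and — if the
four vertices are distinct and $w_{AC} > w_{AD}$, $w_{BD} > w_{BC}$ —
transfers an amount $\bar w$ from the two heavy edges to the two weak
ones (which are created if absent).  Any $\bar w$ conserves all four
strengths; the two rules offered are:

* **Maximum weight** (`max_weight`): the largest transfer keeping every
  weight inside its bounds.  In an unbounded graph this zeroes out (and
  removes) at least one heavy edge per applied switch, mirroring the
  classic discrete switching algorithm; suited to sparse graphs.
* **Constant variance** (`constant_variance`): the unique nonzero root
  $\bar w = (w_{AC}+w_{BD}-w_{AD}-w_{BC})/2$ of the condition that the
  sample variance of the edge-weight assignment is unchanged.  Steps that
  would push any weight outside $[0,\text{ub}]$ are discarded whole
  (they are rare in practice).  Suited to dense, bounded graphs, where
  the maximum-weight rule would pile weights onto the bounds and
  drastically thin the graph.

`rewire_weighted()` defaults to choosing by edge density (constant
variance above density 0.5).  On 0/1 graphs both rules reduce to the
classic switch: $\bar w = 1$ when the switch is admissible.  The
variance the constant-variance rule preserves is that of the weight
assignment over *all* vertex pairs (absent edges as zeros); that is the
quantity asserted to $10^{-9}$ after full runs.

The iteration budget is `ceiling(T * m)` *proposals*, rejected proposals
included — this makes runtime predictable and puts the mixing diagnostics
on the natural one-proposal-per-edge scale.  `mixing_diagnostic()` tracks
the variation of information between the clustering of the $T$-randomized
graph and of the original, plus size and variance ratios; the VI curve
rises to a plateau around $T = 1$, and the default $T = 100$ is far past
it.  One clustering RNG seed is held fixed across the whole $T$ grid so
that $T = 0$ (the identity) reports VI exactly 0 even for stochastic
algorithms: the curve isolates graph mixing from algorithm randomness.
The acceptance suite checks the plateau on the built-in benchmark at
$\lambda = 15$ (the canonical moderately-structured setting): the median
over ten seeds of $VI(1)/VI(100)$ must reach 0.9.

Orientation conventions the description above leaves open are fixed as
follows: the first drawn edge is $(A,C)$ and the second $(B,D)$, each
edge's endpoint order randomised by a fair coin; the strict-inequality
acceptance condition applies to both transfer rules (it guarantees
$\bar w > 0$); absent weak edges enter with weight 0.  The step loop is
compiled (Rcpp) and driven by R's RNG, so runs are reproducible with
`set.seed()`.

## Significance reports

`evaluate_significance()` clusters the original graph once per algorithm,
then re-clusters and re-scores each of `n_null` rewired graphs (default
100, giving percentile resolution 0.01, one clustering per null graph).
Per (algorithm, score) it reports the original value, the null mean over
defined values, the **relative score** (original over null mean — values
far from 1 signal structure), and the **percentile rank** of the original
in the null distribution with mid-rank ties.  Partitions that collapse to
one cluster or to all singletons are scored but flagged: their
external-connectivity scores are trivially optimal and carry no
information.  Internal density is the standard cautionary example — it
favours many small clusters and can genuinely prefer the null.

## Bootstrap stability

`boot_stability()` resamples the *vertices* with replacement, builds the
induced graph (copies of the same vertex joined into a clique of heavy
edges — the upper bound when one exists, otherwise draws from the top 5%
of the original weights), perturbs every edge weight with truncated
normal noise, re-clusters, and compares each replicate partition to the
original partition pulled back through the resample map (a copy inherits
its source vertex's label — the only well-defined alignment under
resampling).  Defaults: `R = 999` replicates; noise standard deviation
`0.1 * sd(original weights)`, tying the perturbation scale to the weight
distribution so it stays "small" across networks of different units; the
clique choice for three or more copies maximises their cohesion.
Similarity is summarised by VI (a true metric, 0 iff equal), the adjusted
Rand index, and the normalized reduced mutual information; a
switching-randomized baseline run provides the no-structure reference.
Degenerate replicates are kept in the distributions but counted, and
failed algorithm runs are recorded as missing, not zero.

## Partition similarity and counting contingency tables

All measures are built on the contingency table of the two labelings,
with natural logarithms throughout so that the $\frac1n\log\Omega$
penalty of the reduced mutual information shares units with the
entropies.  The Rand index is reported as the agreement fraction in
$[0,1]$ (the raw pair-type count divided by $\binom n2$).  Plain and
normalized mutual information inflate for trivial partitions — an
all-singletons labeling attains the maximum against *any* partition,
which would make failed algorithms look maximally stable.  The reduced
mutual information subtracts the information content of the table itself,
$\mathrm{RMI} = I - \frac1n\log\Omega(a,b)$, where $\Omega(a,b)$ counts
nonnegative integer matrices with the observed margins; the normalized
form divides by the average self-RMI of the two labelings.

`count_contingency_tables()` offers three routes and picks automatically:

* **exact** — memoized depth-first enumeration, used whenever the
  enumeration bound stays within $10^7$ states;
* **analytic** — for tables where either partition has at most two
  clusters, an exact elementary closed form (bounded-composition
  convolution); otherwise a maximum-entropy saddle-point estimate of
  $\log\Omega$: fit the geometric mean-parametrization
  $\mu_{rs} = z_ry_s/(1-z_ry_s)$ to the margins, evaluate the tilted
  generating function, integrate the Gaussian fluctuations (projecting
  out the scale-redundancy mode), and apply the second-order Edgeworth
  correction from the third and fourth cell cumulants.  Against exact
  enumeration on random partition-derived tables ($n \le 40$, up to four
  clusters a side) the estimate stays within 2% of $\log\Omega$, which
  the acceptance suite asserts; accuracy degrades when margins contain
  many ones, which is exactly the next regime:
* **mc** — a hybrid for unit-heavy margins: margins are sorted, each
  unit row/column is pinned to a designated heavy column/row, the
  pinning probability is estimated by uniform sampling of tables with
  the diamond-move Markov chain ($\pm1$ on a $2\times2$ minor, a
  uniform-stationary chain on the table lattice), and the remaining core
  is counted exactly or analytically.  The estimator's standard error is
  propagated on the log scale and reported; tests require agreement with
  exact counts within three standard errors.

## The benchmark generator

`sample_wsbm()` plants communities by a block-expectation construction:
given block sizes and a symmetric matrix $E$ of expected pair weights, it
performs a fixed number of steps, each adding a unit of weight to one
pair of distinct vertices chosen with probability proportional to
$E_{b(u)b(v)}$.  The step count is the rounded total expectation
$\sum_i \binom{|C_i|}{2} E_{ii} + \sum_{i<j}|C_i||C_j| E_{ij}$, so the
total sampled weight is *fixed* across samples and each pair's weight is
marginally binomial.  Self-pairs are excluded from both the count and the
sampling — the only reading under which the per-step probabilities sum to
one over admissible pairs; the plain half-sum over all ordered block
pairs (which counts diagonal self-pairs) is available behind
`self_pairs = TRUE` for comparison, and rounding is half-up.

The built-in benchmark (`wsbm_benchmark_spec()`) uses block sizes
(40, 25, 25, 10) and a fixed base matrix whose diagonal is scaled by
$\lambda$: at $\lambda = 1$ the expected weight is nearly uniform
(the step count is 108), while large $\lambda$ plants strong
communities.  `lambda_sweep()` samples graphs across $\lambda$, clusters
them, and records VI and ARI against the planted partition.  With 20
samples per $\lambda$, Louvain's exact-recovery rate (ARI = 1) crosses
95% at $\lambda = 25$ in the swept grid {5, 10, 15, 20, 25, 31, 35} —
comfortably below the $\lambda \approx 30$ scale at which all algorithms
recover the planted structure.  `scripts/acceptance.R` recomputes exactly
this threshold.

## What the synthetic benchmark does and does not show

The generator produces integer (count-like) weights with a fixed total,
independent pair draws, balanced-to-moderately-skewed block sizes, and no
degree heterogeneity within blocks.  Real weighted networks add features
it does not emulate: heavy-tailed strength distributions, correlated
weights (e.g. correlation networks are complete graphs with bounded,
strongly dependent weights), hierarchical or overlapping communities, and
weight-topology coupling.  Passing the benchmark suite therefore shows
that the machinery is correct and that the methods behave as designed on
planted structure of tunable strength — not that any particular real
network will be as cleanly separable.  The significance and stability
reports are comparative tools, not hypothesis tests with calibrated error
rates.

## Numerical choices and problem sizes

Strength and total-weight conservation of the switching model are exact
in exact arithmetic; floating-point accumulation over tens of thousands
of transfers leaves relative drift near machine precision, and the suite
asserts $10^{-9}$.  Report reproducibility is exact under a fixed seed.
Whole-report invariance under weight scaling is asserted with
$\varphi = 4$: powers of two make the scaled switching trajectory
bitwise-coherent with the unscaled one, isolating the mathematical
property from rounding divergence.  The test and acceptance runs use
deliberately modest sizes — benchmark graphs of 100 vertices, null
ensembles of 8–50, bootstrap runs of up to 100 replicates, exhaustive
partition enumeration up to $n = 5$ with sampled pairs up to $n = 8$ —
chosen so the full suite completes in about two minutes while still
exercising every code path at meaningful scale; all of them scale up by
changing the corresponding arguments.

## Known limitations

Directed and signed graphs are out of scope (weights must be
nonnegative; rewiring and scoring assume symmetry).  Multi-edges are
collapsed by summation at input.  The partition-level aggregation choice
(plain mean over clusters) is one of several defensible conventions;
per-cluster local significance is not implemented.  The saddle-point
$\Omega$ estimate should not be trusted for margins dominated by ones —
use the hybrid Monte Carlo route there (the automatic selector does).
Median degrees are computed and exposed with the other aggregates but no
bundled score consumes them.
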