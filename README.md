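# clustvalid

Significance and stability assessment for clusterings of weighted
networks.

Community-detection algorithms (Louvain, Walktrap, label propagation, …)
return a partition for *any* graph, structured or not.  For networks
whose true organisation is unknown — correlation networks between
currencies or time series, interaction-count social networks, email
graphs — the hard question is whether a clustering means anything.
clustvalid answers it on two axes:

* **Significance.**  A catalogue of community scoring functions adapted
  to weighted graphs (internal density, conductance
  `c̃_S / (2m̃_S + c̃_S)`, normalized cut, out-degree fractions, a
  threshold-integral weighted clustering coefficient
  `C̃ = (1/w̄) ∫₀^w̄ C_t dt`, modularity) is evaluated on the partition of
  the original graph and on partitions of graphs drawn from a
  **degree-preserving switching null model**: repeated two-edge switches
  transfer weight from heavy edges to weak ones, conserving every
  vertex's strength, with a maximum-weight rule for sparse graphs and a
  variance-preserving rule for dense bounded ones.  Scores are reported
  relative to the null mean and as percentile ranks in the null
  distribution.
* **Stability.**  A nonparametric vertex bootstrap with edge-weight
  perturbation: resample vertices with replacement, induce the graph,
  join duplicate copies by heavy edges, jitter weights with truncated
  normal noise, re-cluster, and compare to the original partition via
  variation of information, adjusted Rand index and the **normalized
  reduced mutual information** `RMI = I − (1/n) log Ω(a,b)`, whose
  contingency-table count Ω is computed by exact enumeration, an
  analytic saddle-point estimate, or a hybrid Markov-chain Monte Carlo
  method depending on the margins.

A **weighted stochastic block model** generator supplies benchmark
graphs with planted communities of tunable strength λ (block sizes
40/25/25/10 built in), used throughout the tests and the acceptance
script.

## Worked example

Sample a benchmark graph with four planted blocks at moderate strength
(λ = 15), then ask whether the clusterings found in it are significant
and stable:

```r
library(clustvalid)

smp <- sample_wsbm(wsbm_benchmark_spec(15), seed = 1)
g <- smp$graph     # 100 vertices, total weight fixed at 622

report <- evaluate_significance(g, algorithms = c("louvain", "walktrap"),
                                n_null = 50, seed = 42)
subset(report, score %in% c("internal_density", "conductance", "modularity"))
```

```
 algorithm            score original null_mean relative percentile
   louvain internal_density    0.350     0.355    0.987       0.46
   louvain      conductance    0.184     0.638    0.289       0.00
   louvain       modularity    0.486     0.214    2.273       1.00
  walktrap internal_density    0.357     0.541    0.660       0.02
  walktrap      conductance    0.174     0.794    0.220       0.00
  walktrap       modularity    0.480     0.158    3.035       1.00
```

Both algorithms find partitions whose conductance sits at the 0th
percentile of the null distribution (lower is better) and whose
modularity sits at the 100th (higher is better): clear structure.
Internal density illustrates why it is a poor lone criterion — for
Louvain it is indistinguishable from the null (percentile 0.46), because
it rewards many small clusters rather than genuine separation.

```r
st <- boot_stability(g, "louvain", R = 50, include_null_baseline = TRUE,
                     seed = 42)
st$summary
```

```
  baseline algorithm measure   mean  n n_degenerate n_failed
1    FALSE   louvain     ari 0.6463 50            0        0
2     TRUE   louvain     ari 0.1674 50            0        0
3    FALSE   louvain    nrmi 0.6850 50            0        0
4     TRUE   louvain    nrmi 0.0807 50            0        0
5    FALSE   louvain      vi 0.7536 50            0        0
6     TRUE   louvain      vi 2.3880 50            0        0
```

Bootstrap replicates of the real graph stay close to the original
clustering (mean ARI 0.65, mean VI 0.75 nats), while the same procedure
on a switching-randomized baseline collapses (ARI 0.17, VI 2.39): the
clustering is far more stable than chance.  And indeed the found
partition matches the planted one exactly:

```r
adjusted_rand_index(smp$membership, cluster_adapter("louvain")(g))
#> [1] 1
```

A thin command-line front end over the same functions is installed at
`inst/cli/clustbench.R` (subcommands `score`, `rewire`, `wsbm`,
`compare`, `significance`, `stability`, `pipeline`).

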