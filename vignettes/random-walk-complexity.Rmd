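---
title: "Random-walk complexity of weighted networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk complexity of weighted networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The measure

`netcomplexity` treats the complexity of a weighted network as a convex
function of disorder: it is smallest for the fully ordered reference state
(a ring lattice, RL) and for the fully disordered one (an Erdős–Rényi
random graph, ER), and largest somewhere in between, where a network mixes
order and disorder as small-world topologies do. The probe is a
strength-biased random walk: a walker at node $i$ steps to $j$ with
probability $p_{ij} = w_{ij} / \sum_j w_{ij}$, and the sequence of visited
node strengths $str_i = \sum_j w_{ij}$ forms a scalar time series whose
regularity reflects the network's large-scale structure — community
structure produces repetitive visiting patterns, heterogeneous hubs
produce irregular ones.

The regularity of the series is quantified by its sample entropy
$\mathrm{SampEn}(m, r)$: the negative log conditional probability that two
segments matching for $m$ points (Chebyshev distance $\le r$) also match
for $m+1$ points, with self-matches excluded. We use the conventional
$m = 2$ and $r = 0.2\,\sigma$ of the analysed series.

The **local complexity** of node $i$ compares the entropy of the network
with node $i$ deleted against matched null ensembles:

$$
c_i \;=\; 100\, p_i\, \frac{(H_{\neq i} - \bar H_{ER})\,(H_{\neq i} - \bar H_{RL})}{H^2},
$$

where $H_{\neq i}$ is the walk-series entropy of the node-removed network,
$\bar H_{ER}$ and $\bar H_{RL}$ are mean entropies over ensembles of ER and
ring-lattice networks of the same size ($n-1$) and edge count with edge
weights drawn from a kernel-density estimate of the observed weights,
$p_i$ is the probability of node $i$ appearing in the intact-network walk
series, and $H$ is the intact network's walk entropy. The **global
complexity** is the sum $C = \sum_i c_i$. The product form makes $c_i$
vanish when the reduced network is entropy-indistinguishable from either
reference, and the formula is applied literally — negative values occur
when $H_{\neq i}$ falls between the two null means, and are kept (a
`clamp_negative` option exists but is off by default).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `n_steps` (T) | 25,000 | steps | walk entropy stabilises beyond ~23,000 points (`sampen_length_profile()` reproduces this) |
| `n_walkers` (K) | 1 | walkers | one long series per network; per-walker entropies are averaged when K > 1 |
| `m` | 2 | — | standard embedding dimension for SampEn |
| `r_factor` | 0.2 | × series sd | standard relative tolerance; population sd of the analysed series (a pooled sd can be supplied) |
| `ensemble_size` | 1,000 | networks | full-scale null ensembles; reduced sizes (50–200) are used at desk scale, at the cost of larger Monte-Carlo error in $\bar H_{ER/RL}$ |
| `q` (FDR) | 0.05 | — | Benjamini–Hochberg level for connectivity edge selection |

`p_i` defaults to the analytic stationary distribution
$str_i / \sum_j str_j$ for undirected networks — it is what the empirical
visit frequency converges to, and is deterministic; an `"empirical"` mode
uses the intact walk's visit frequencies instead.

## Null-model construction

Both null generators match the node-removed network's size and edge count:
ER nulls draw exactly that many edges uniformly (G(n, M)); ring-lattice
nulls use the nearest even degree to the average degree $2M/n$ (round half
up, clamped to the feasible range). An exactly degree-distribution-
preserving random graph would not be an ER graph, so edge-count (average
degree) matching is used. Weights are sampled from a Gaussian-kernel
density estimate (Silverman bandwidth) of the pooled nonzero weights of
the intact network, by kernel resampling; negative draws are redrawn
(`truncate-at-zero`) so weights stay positive. Truncation slightly raises
the mean when the source distribution abuts zero — the tests assert the
exact truncated-mixture mean rather than the source mean. A permutation
of observed weights is available as an alternative null.

Two implementation choices keep the pipeline tractable and well-defined:

* **Ensemble caching.** A null ensemble depends on the removed network
  only through $(n-1, M)$ and the shared weight sampler, so nodes whose
  removal leaves the same edge count share one ensemble
  (`null_cache = TRUE`). This typically cuts the dominant cost several
  fold and cannot change what is being estimated; sub-seeds are keyed by
  edge count, so cached and uncached runs are bit-identical.
* **Canonical node order.** Walks are simulated with nodes sorted by
  label, removed-network walks are seeded by the removed node's label,
  and ensembles by edge count; consequently the whole result depends only
  on the labelled network, not on the row order of the matrix it arrived
  in.

## The reference-state floor

At the reference states the measure attains a *minimum*, not exactly
zero. Writing $H_{\neq i} = \mu + \delta_i$ with $\mu$ the matching null
mean, both factors of $c_i$ share the same realization $\delta_i$, so
$\mathbb{E}[c_i] \approx 100\, p_i\, \mathrm{Var}(H_{\neq i}) / H^2 > 0$.
That variance is dominated by genuine network-to-network entropy
variability (for ER graphs of ~40 nodes, entropy sd ≈ 0.066 against a
walk-noise sd ≈ 0.015 at $T = 10^4$), so it is not removable by longer
walks, more walkers, or larger ensembles. At desk scale the floor is
about $4\times 10^{-3}$ per node for ER inputs — small in absolute
terms, but reliably positive, and resolvable from zero with modest
replication.

A second, systematic contribution comes from the null weights: kernel
smoothing with zero-truncation shifts the null weight distribution of a
zero-adjacent source (such as uniform (0,1) weights) and measurably
raises null-ensemble entropies (≈ +0.03–0.04 at the sizes above; the
`"reflect"` boundary rule roughly halves this). At the reference states
one factor of the product is the full lattice–ER entropy gap, so this
small offset is amplified into the endpoint complexities. At reduced
scale (e.g. $n = 50$, 5,000-step series, 50-network ensembles) the
resulting endpoint inflation together with replicate noise can be of the
same order as the interior small-world peak, in which case the convex
profile is not statistically resolvable from a handful of replicates —
a limitation of the measure at small ensemble sizes that users comparing
networks should budget replicates for.

## What the synthetic generators emulate

`generate_ws()` produces Watts–Strogatz networks (ring lattice, per-edge
rewiring with probability $p$, weights uniform on (0,1)), spanning the
order–disorder spectrum that the sweep harness (`complexity_sweep()`)
profiles: the measure is constructed so that $C$ is small at $p = 0$ and
$p = 1$ and larger in between. Resolving that profile requires the
Monte-Carlo error of each cell to be small against the interior–endpoint
separation; see the bias discussion below for why desk-scale sweeps may
not resolve it.

`synth_roi_signals()` produces Gaussian multivariate series with block
correlation structure, designated anticorrelated pairs, and a shared
global component. This exercises the full connectivity pipeline —
Pearson correlations, t-distribution p-values, BH-FDR edge selection,
sign splitting into `pos`/`neg`/`abs` networks (with the exact identity
`abs = pos + neg`), and global-signal regression, which uncovers the
anticorrelations a strong shared component masks. It does **not**
emulate haemodynamics, autocorrelated noise, scanner drift, or parcellation
error; passing tests demonstrate the statistical pipeline's correctness,
not robustness to those real-data features.

## Numerical choices

* SampEn uses closed tolerance ($d \le r$) and excludes self-matches; the
  variant that keeps self-matches and the per-level averaged-probability
  index ranges is available (`self_matches = TRUE`) and is biased toward
  regularity, strongly so for sparse-match continuous series.
* The embedding distance uses $m$ components at level $m$ and $m+1$ at
  level $m+1$ (the standard convention).
* Undefined entropies (no template matches at either length) are flagged
  (`NA` + counter), never replaced by a number; ensemble means skip them
  and report the count.
* A walker at a node with zero out-strength restarts uniformly over
  non-isolated nodes by default, keeping the series length fixed; an
  `"error"` rule is available.
* Isolated transition-matrix rows are all-zero, never silently uniform.
* Global efficiency maps weights to lengths via $l_{ij} = 1/w_{ij}$
  (configurable to unit lengths); unreachable pairs contribute zero.
* The weighted clustering coefficient is implemented in its directed form
  and reduces exactly to the classical binary coefficient on binary
  symmetric input; weights above 1 are rescaled by the maximum with a
  warning.
* All randomness flows through R's RNG; every per-node, per-replicate,
  per-cell computation derives a sub-seed from the master seed and a
  stable tag, so partial reruns and out-of-order execution reproduce.

## Problem sizes used by the test-suite

The shipped tests run the pipeline at desk scale, chosen so the whole
suite completes quickly while keeping Monte-Carlo error below the effect
sizes being asserted: sweep networks of $n = 50$ with 5,000-step series
and 50-network ensembles over $k \in \{6, 10\}$,
$p \in \{0, 0.05, 0.2, 0.5, 1\}$, 5 replicates; reference-state checks on
$n = 40$ networks with 10,000-step series, five replicate inputs per
state; oracle equivalences on series up to $N = 200$ and networks up to
$n = 15$. Full-scale analyses ($n = 100$, $T = 25{,}000$, ensembles of
1,000) use the same code paths.

## A worked example

```{r, eval = FALSE}
library(netcomplexity)

net <- generate_ws(50, 6, 0.2, seed = 1)
res <- network_complexity(net, n_steps = 5000, ensemble_size = 50, seed = 1)
res$global_value
head(res$per_node)

m <- graph_metrics(net)
c(segregation = m$clustering_total, integration = m$efficiency)
```

## Known limitations

* Walk series on directed networks are supported, but the analytic
  stationary distribution is not; use the empirical visit frequencies.
* The null ensembles match edge count and weight distribution, not the
  degree sequence; strength-per-node matching is deliberately not
  attempted.
* The complexity of a single network is a Monte-Carlo estimate; at
  reduced ensemble sizes the per-node values carry error of order the
  null-ensemble standard error, and comparisons between nodes should use
  replicate runs.
* Negative local complexities are legitimate outputs of the literal
  product form; interpretation of their sign rests with the analyst.
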