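---
title: "Silhouette community detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette community detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdnet)
```

## The model

`scdnet` treats community detection as unsupervised structure recovery in an
embedding space. A weighted undirected network $G = (N, E, w)$ is mapped by
an embedding $f : N \to \mathbb{R}^d$ to a matrix of node vectors; a
clustering $c$ of those vectors induces a partition $P(G) = c(f(G))$; and
the quality function being maximized is the global Silhouette of the
clustering:

$$
s(i) = \frac{b(i) - a(i)}{\max\{a(i), b(i)\}}, \qquad
\mathrm{Silhouette}(P) = \frac{1}{|N|} \sum_{i \in N} s(i),
$$

with $a(i)$ the mean Euclidean distance from point $i$ to the rest of its
cluster, $b(i)$ the smallest mean distance to any other cluster, and
$s(i) = 0$ when $i$ is alone in its cluster (where $a(i)$ is undefined) or
when $a(i) = b(i) = 0$. The detector therefore looks for the embedding
setting $p \in \mathcal{P}$ and cluster count $k \in \mathcal{K}$ whose
k-means clustering is geometrically most coherent — it performs no
modularity optimization at any point, which is what distinguishes it from
Louvain-style detectors.

The working assumption is that the embedding preserves community structure
as spatial proximity: nodes sharing most of their neighborhood land close
together, so a good partition of the graph appears as a well-separated
clustering of the vectors. When that assumption fails (embeddings of
near-regular or extremely sparse graphs carry little geometry), the
Silhouette criterion has nothing to work with; see *Limitations*.

## Embedders

**NetMF** (`embed_netmf`). DeepWalk-style random-walk embeddings implicitly
factorize the matrix

$$
M = \log^+\!\Big(\frac{\mathrm{vol}(G)}{b}\Big(\frac{1}{T}
\sum_{r=1}^{T}(D^{-1}A)^{r}\Big)D^{-1}\Big),
$$

where $T$ is the context window, $b$ the number of negative samples, $A$
the weighted adjacency, $D$ the diagonal of generalized degrees and
$\mathrm{vol}(G) = \sum_{ij} A_{ij}$. Two numerical choices are deliberate:

- $\log^+$ is the *truncated* logarithm $\log(\max(x, 1))$. Applying the
  raw $\log(\cdot) - \log b$ to zero entries would produce $-\infty$; the
  clip at 1 is the standard NetMF device, keeps $M \ge 0$ and finite, and
  is where the factor $1/b$ (folded into the argument) acts for entries
  above the clip.
- the embedding is $U_d \sqrt{\Sigma_d}$ from the rank-$d$ SVD — the usual
  NetMF scaling, recorded in the embedding's provenance attribute. The SVD
  is dense LAPACK, hence deterministic; the `seed` argument is recorded for
  interface uniformity.

$M$ is computed densely, which is the right trade-off up to the
$\sim 10^4$-node graphs the generators target; powers of the transition
matrix fill in quickly, so a sparse representation would not help.

**Personalized PageRank** (`embed_ppr`). Each node's feature vector is the
stationary distribution of a random walk restarting at that node with
probability $1 - \alpha$ (damping $\alpha = 0.85$ by default), obtained by
power iteration to an L1 tolerance of $10^{-6}$. Design choices: undirected
edges are walked in both directions with weight-proportional transition
probabilities; the iteration is restricted to the seed's connected
component (the "shrinking" of the name — a pure speedup, since unreachable
nodes receive exactly zero mass); dangling mass restarts at the seed so the
iterates remain probability vectors. Rows may optionally be L2-normalized
before clustering (`normalize = TRUE`, off by default): raw PPR rows are
simplex vectors whose scale k-means is sensitive to, but since no
normalization scheme is canonical for this use, the package exposes the
option rather than imposing it.

## Clustering and the k search

Clustering is mini-batch k-means with k-means++ initialization, Euclidean
distance throughout, `n_init = 3` restarts, and the lowest-inertia run kept.
With `batch_size >= n` (the default for networks up to 1024 nodes) the
update reduces to exact full-batch Lloyd iterations; above that, Sculley's
per-center learning-rate updates are used. Empty clusters are legal; the
reported community count is the number of *non-empty* clusters.

The search over $k$ is two-stage:

1. **Coarse**: evaluate $k$ over the arithmetic grid
   `valid_range(k_min, K, gamma)` — stride $\gamma$, with $K$ appended if
   the stride does not land on it. The analytic default is
   $\gamma = \lceil K^{2/3} \rceil$ (`gamma_estimate`), which balances the
   number of coarse evaluations against the resolution of the grid; the
   ceiling keeps $\gamma \ge 1$ and never increases the evaluation count
   relative to the floor.
2. **Fine**: exhaustively inspect the $\pm\gamma$ neighborhood of the
   coarse optimum $k^*$, scanning outward ($k^*\!-\!1, k^*\!+\!1,
   k^*\!-\!2, \dots$). The outward order is a deliberate choice: it makes
   the stopping rule meaningful, since evaluations near the current optimum
   are the informative ones.

Both phases halt after `w` consecutive non-improving evaluations
(default `w = 5`). Every evaluation is recorded in a trace; the returned
partition is the argmax, re-derived deterministically from the per-$(p,k)$
seed, so the full pipeline is reproducible from `config + seed` alone.

**Cross-dimension comparison.** Silhouette values computed in spaces of
different dimension are not directly comparable (higher-dimensional
embeddings systematically compress the score range). When the grid spans
several dimensions, raw Silhouettes are min–max normalized *within each
dimension* before the cross-grid argmax. This is a documented stand-in for
a calibration whose exact published form is not available to us; it is a
design choice of this package, and `normalize_across_dims = FALSE` restores
raw comparison. A side effect worth knowing: each dimension's best
evaluation normalizes to 1.0, so cross-dimension selection reduces to the
tie-break — smaller $k$, then smaller $d$, then earlier grid order — a
deterministic, parsimony-biased rule.

**Cost control.** One global Silhouette costs $O(|N|^2 d)$; for networks
above 5000 nodes a seeded uniform subsample of 5000 points is scored
instead (override with `subsample`).

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `K` | — | largest community count considered |
| `k_min` | 5 | smallest candidate k (2 is sensible for tiny graphs) |
| `gamma` | `"auto"` = ⌈K^⅔⌉ | coarse-grid stride |
| `w` | 5 | stopping window (non-improving evaluations per phase) |
| `T_window`, `b`, `d` | 3, 1, 32 | NetMF window, negative samples, dimension |
| `alpha`, `tol` | 0.85, 1e-6 | PPR damping and convergence threshold |
| `batch_size` | min(n, 1024) | k-means batch (full-batch below 1024) |
| `n_init` | 3 | k-means restarts |
| `subsample` | off ≤ 5000 nodes | Silhouette subsample size |

The preset `embedding_grid("benchmark-grid")` spans
$b \in \{1,5,20\} \times T \in \{1,3,5,10,30,50\} \times d \in
\{16,32,64,128,256\}$ (90 settings) for exhaustive sweeps;
`"fast-grid"` (NetMF $d \in \{16, 32\}$) is the default.

## Synthetic generators: what they emulate and what they do not

`generate_sbm` draws Bernoulli planted partitions (delegating to igraph)
and is the fixture of choice for exact, fast, deterministic tests: blocks
of equal size, homogeneous degrees, tunable separation via
$p_{in}/p_{out}$.

`generate_lfr` implements the Lancichinetti–Fortunato–Radicchi construction
directly: truncated power-law degrees (exponent 2 by default; the lower
cutoff is solved numerically so the continuous law matches the requested
mean), power-law community sizes (exponent 1), a capacity-respecting
node-to-community assignment with the classic kick-out step, and
configuration-model stub matching for internal edges per community and
external edges globally, with the mixing parameter $\mu$ setting the
external fraction of each node's edges. Two departures from an idealized
LFR are worth stating plainly:

- stubs that cannot be matched after bounded rewiring rounds are dropped,
  so realized mean degree runs a few percent below the target (the test
  suite bounds the shortfall at 20%); realized mixing tracks $\mu$ within
  about 0.05;
- community-size bounds are derived from the internal-degree distribution
  rather than taken as independent inputs.

Passing tests on these generators show that the method recovers *planted,
assortative, non-overlapping* communities under power-law degree
heterogeneity. They say nothing about overlapping or hierarchical
communities, degree-corrected block structure, or networks whose
communities are not embedding-separable — real data can fail in all of
these ways.

The benchmark harness (`scd_benchmark`) mirrors the published experimental
design: candidate range $[5, |N|]$ in strides of 10, stopping window 5, one
NetMF setting ($T = 3$, $b = 1$, $d = 32$). The full benchmark grid of 420
parameter combinations (nodes up to $10^4$) is enumerable via
`lfr_benchmark_grid("full")`, but the package's own study sizes are the
*reduced* grid — nodes $\{100, 500, 1000\}$, 18 feasible specs at mixing
0.1 — which one CPU completes in about a minute.

## Observed behavior on the reduced benchmark

On the reduced mixing-0.1 grid the mean NMI of SCD-NetMF lands around
0.89–0.91 depending on the seed (the acceptance script recomputes this).
The shortfall relative to near-perfect recovery is concentrated in
instances with *few, large* true communities — e.g. $n = 100$ with average
degree equal to the maximum degree 50, which forces two near-clique
communities. There the embedding contains many (near-)duplicate rows, and
maximizing the Silhouette genuinely prefers splitting them into small
groups of duplicates: over-estimation of the community count in the
few-community regime is a property of the criterion, not an implementation
artifact, and disappears as the number of true communities grows. Equal-size
SBM fixtures with $p_{in} = 0.8$, $p_{out} = 0.02$ are recovered at
18–20/20 across seeds.

## Degenerate inputs and tie-breaks

- Graphs with isolated nodes are rejected by the embedders with an
  instruction to remove them (PPR of an isolated seed would be the trivial
  restart distribution; NetMF's $D^{-1}$ is undefined).
- `k` larger than the number of distinct embedding rows: the distinct rows
  are clustered, with a warning.
- A clustering that realizes fewer than 2 non-empty clusters has no defined
  Silhouette; the evaluation records `NA` and counts as non-improving.
- Metric degenerate cases: NMI of two zero-entropy labelings is 1 (they are
  necessarily identical), one-sided zero entropy gives 0; ARI returns 1
  when both partitions are trivially equal fixed points of the formula
  (the $max = expected$ cancellation).
- All tie-breaks (k-means assignment, argmax over the trace) are
  deterministic: first index, then smaller $k$, smaller $d$, earlier grid
  order.

## Limitations

- Non-overlapping, flat communities only.
- The Silhouette evaluation is the bottleneck ($O(|N|^2 d)$ per $k$);
  subsampling makes $10^5$-node graphs feasible but trades variance for
  time.
- PPR embeddings are full $|N|$-dimensional stationary distributions;
  on networks whose communities differ mainly in density rather than
  reachability they underperform NetMF, and whole-distribution features
  are likely not the optimal reduction.
- The method inherits the embedding's failure modes: regular graphs, very
  sparse graphs and graphs with strong core–periphery (rather than
  assortative) structure embed with little usable geometry.
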