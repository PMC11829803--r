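---
title: "Trajectory inference with communication-weighted cell graphs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory inference with communication-weighted cell graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Trajectory inference orders single cells along differentiation paths from a
snapshot expression matrix. Most methods rely solely on transcriptional
similarity between cells. This package additionally exploits intercellular
communication: during development, signalling between cells (ligand secreted
by a sender, receptor expressed by a receiver) accompanies and constrains
lineage progression, so ligand–receptor co-expression between cell
neighbourhoods carries information about which cell states are adjacent on
the differentiation path.

The pipeline has four stages.

**1. Communication scoring.** Cells are grouped (user labels, or k-means
with the cluster number chosen by the Gap statistic). For each
ligand–receptor pair $k = (L, R)$ and ordered group pair $(i, j)$ a
mass-action score with Hill-type saturation is computed,
$$C^k_{ij} = \frac{\bar L_i \, \bar R_j}{k_h + \bar L_i \, \bar R_j},$$
with $\bar L_i$ the mean ligand expression in group $i$ (zero when the gene
is absent) and $k_h = 0.5$ by default. The score is projected to cell pairs:
for sender $p \in i$ and receiver $q \in j$,
$$P_{pq} = \sum_{k} C^k_{ij} \,\mathbf{1}[L_p > \tau]\, \mathbf{1}[R_q > \tau],$$
a directed cell-by-cell communication matrix gated by *valid expression*
(strictly above the threshold $\tau = 1$ on the log scale). $P$ is
symmetrized by the arithmetic mean and min–max scaled to $[0,1]$ before it
enters the graph, because the downstream edge weights are undirected and the
scaling keeps one sweep grid meaningful across datasets.

**2. Communication-weighted fuzzy kNN graph.** Cells are embedded with PCA
(50 components). For each cell $i$ and its $k$ nearest neighbours,
$$p_{i|j} = \exp\!\big(-(d(x_i, x_j) - \rho_i)/\sigma_i\big),$$
where $\rho_i$ is the distance to the nearest neighbour — so every cell
keeps one edge of weight 1, which protects local connectivity — and
$\sigma_i$ is calibrated by binary search so that
$\sum_j p_{i|j} = \log_2 k$, the standard smooth-kNN calibration
($2^{\sum p} = k$). Conditional probabilities are symmetrized by the fuzzy
union $p_{ij} = p_{i|j} + p_{j|i} - p_{i|j}p_{j|i}$, and communication
information is added on the existing support:
$$\hat p_{ij} = p_{ij} + K\, S_{ij},$$
with $K \ge 0$ the communication weight. $K = 0$ bypasses communication
entirely; the weight is the pipeline's central tuning parameter.

**3. Abstraction and lineage.** Louvain community detection partitions the
graph (resolution-scaled modularity). Partition-level connectivity is the
observed inter-partition edge count over the count expected under uniform
random edge placement, clipped to $[0, 1]$. Differentiation potency is
measured per cell as the entropy of functional-group activation (with no
grouping supplied, the natural log of the expressed-gene count): committed
cells express narrow programs and score low. Each partition is summarized by
its *stable-state* entropy — the mean over its 25% lowest-entropy core —
so transition-state cells do not blur the ordering. Edges are oriented from
high to low stable-state entropy, and the lineage tree is the maximum-weight
spanning arborescence (Chu–Liu/Edmonds) rooted, per weakly-connected
component, at the highest-entropy partition.

**4. Pseudotime.** The root cell is the highest-entropy cell of the
highest-entropy partition. Diffusion pseudotime is computed on the
communication-weighted graph: density-normalized kernel, symmetrized
transition operator, eigendecomposition; the accumulated operator scales the
top `n_dcs` non-stationary eigenpairs by $\lambda/(1-\lambda)$ and
pseudotime is the Euclidean distance to the root's row. Cells outside the
root's connected component receive `Inf` — disconnected topologies are a
supported outcome, not an error.

**Evaluation.** Orderings are scored against external ordinal labels (stage,
sampled time) with a signed pair-concordance score in $[-1, 1]$: over all
cell pairs with distinct labels, concordant minus discordant over
comparable, with pseudotime-tied pairs (including pairs that are both
infinite) scoring zero. The score is invariant under strictly monotone
transformations of pseudotime and equals Kendall's tau-a restricted to
label-distinct pairs on tie-free input.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `expr_threshold` | 1 | valid-expression gate (log2 scale) for communication and entropy activation |
| `n_pcs` | 50 | PCA dimensions for the neighbour search |
| `n_neighbors` | 10 | kNN size; the calibration target is `log2(k)` |
| `cci_weight` (K) | 1 | communication weight; sweep 0–10 when external labels allow |
| `resolution` | 1 | Louvain resolution; higher values give finer partitions |
| `core_fraction` | 0.25 | stable-state core (ceiling, so cores are never empty) |
| `n_dcs` | 10 | diffusion components; capped at component size − 1 |
| `kh` | 0.5 | Hill constant of the communication score |

The sweep grid runs 0 to 10 inclusive in 0.1 steps — 101 points; the
inclusive endpoint is deliberate so that the no-communication baseline
($K=0$) is always part of the comparison.

## Design choices where the design was open

- **Communication score.** Dedicated communication frameworks aggregate
  curated multi-subunit complexes with trimean statistics and permutation
  tests. Here the score is a deliberately minimal mass-action law with
  Hill saturation over a user-supplied pair table: it preserves the two
  properties the pipeline actually consumes (monotone in ligand and
  receptor expression, bounded in $[0,1)$) and keeps the result exactly
  reproducible. Multi-subunit complexes, cofactors and pathway aggregation
  are out of scope.
- **Entropy.** Potency is scored by deterministic functional-group
  activation entropy with a pluggable gene-to-group mapping, instead of an
  ontology-bootstrap procedure. The pipeline only needs a potency
  *ordering* of partitions, which the activation entropy provides without
  downloads or resampling noise.
- **Directed vs undirected communication.** The cell-level matrix is built
  directed (sender to receiver) and symmetrized by the mean, because the
  graph weights it augments are undirected.
- **Edge counting for connectivity** uses binary edge presence on the
  support of $\hat p$, matching the inter-edge-count definition; a
  weighted variant would conflate edge density with edge strength.
- **Pseudotime runs on $\hat p$** (the communication-weighted graph), not
  on the plain joint probabilities: the weighted graph is the method's
  premise. A flag at the graph-construction level allows the comparison.
- **Ties.** Louvain is seeded and deterministic; stable-state core ties
  break by cell id; equal-entropy partition pairs orient low id to high
  id; equal sweep scores return the smallest $K$. Every tie rule is
  deterministic so that identical configuration and seed give
  byte-identical outputs.
- **Orphan roots.** After entropy orientation a node can be unreachable
  from its component's root (two locally-high-entropy partitions pointing
  into a shared sink). Such nodes become roots of their own subtrees with
  a warning, yielding a forest rather than a hard error.

## Numerical notes

- The $\sigma$ bisection runs 64 halvings between an expanding upper
  bracket and zero. When neighbours are (near-)equidistant — within
  $10^{-9}$ of the distance scale — the target sum is unreachable and the
  search saturates at a large bandwidth, giving all neighbours weight
  $\approx 1$; affected cells are flagged by a warning.
- Eigenvalues entering $\lambda/(1-\lambda)$ are clipped just below 1.
  On *exactly bipartite* toy graphs (an unweighted path) the spectrum
  contains a periodic eigenpair at $\lambda = -1$; including it perturbs
  pseudotime at the far end of the path by ~0.01%, enough to break strict
  monotonicity of the last pair of nodes. Truncation to `n_dcs` well below
  the component size — the normal operating regime — excludes such pairs;
  the test suite checks exact agreement with a closed-form
  matrix-inverse oracle at full rank and strict monotonicity under
  truncation.
- `pmin`/comparison-based PAS counting avoids `Inf - Inf` arithmetic;
  infinite-vs-infinite pairs compare equal and score zero.
- Degenerate inputs: empty matrices, all-equal external labels, negative
  entries, K < 0, empty partitions and isolated roots raise early, typed
  errors; zero-activation cells get entropy 0 with a warning.

## What the synthetic generator does and does not emulate

`generate_lineage()` builds a branching lineage over a rooted tree of
segments: a large pool of potency genes shuts down at gene-specific times
(so the expressed-gene count, hence entropy, decreases along true time);
per-segment marker programs ramp on at segment entry and persist in
descendants (so partitions separate but profiles stay continuous along
every root-to-leaf path — ramps are pinned to exactly zero at boundaries);
and each tree edge plants ligand genes in the parent segment and receptor
genes in the child segment, tapered near the boundary, so communication is
informative about lineage adjacency. Noise is multiplicative lognormal.

This emulates smooth developmental progressions with branch-specific
programs. It does **not** emulate UMI count statistics (dropout,
library-size variation beyond lognormal noise), batch effects, cell-cycle
structure, doublets, or cyclic trajectories. Passing the end-to-end tests
therefore demonstrates that the pipeline recovers planted continuous
branching structure under moderate noise — not that it is robust to the
full failure modes of real scRNA-seq data.

Test and acceptance problem sizes are 600 cells x 200 genes x 2 branches
(noise sd 0.2) for end-to-end recovery, 300 cells for the weight sweep and
200 cells for null controls; these desk-scale sizes keep the full suite
reproducible in minutes while leaving every stage's behaviour observable.

## Known limitations

- The arborescence step cannot represent cyclic trajectories.
- Communication scoring needs a ligand–receptor table; results are only as
  good as the supplied pairs, and cross-species tables are the user's
  responsibility.
- Entropy-based rooting assumes potency decreases along differentiation;
  datasets violating that premise (e.g. dedifferentiation) will be
  oriented incorrectly.
- The exact kNN search is quadratic in cell number; the package targets
  desk-scale datasets (up to a few thousand cells).

## A minimal run

```{r}
library(trajCCI)

syn <- generate_lineage(600, 200, n_branches = 2, noise_sd = 0.2, seed = 1)
cfg <- trajcci_config(seed = 1)
res <- run_trajcci(syn$matrix, lr = syn$lr_table, config = cfg)
res

labels <- time_quartile_labels(syn$true_time)
pt <- res$pseudotime$pseudotime
pas(pt, labels[names(pt)])

sw <- sweep_cci_weight(syn$matrix, syn$lr_table, labels,
                       grid = seq(0, 10, 1), config = cfg)
sw$best_k
```
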