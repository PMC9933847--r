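---
title: "Methods: seed-aware network features and adaptive PU labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-aware network features and adaptive PU labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpu)
```

## Setting and assumptions

Disease-gene prioritization here is a positive-unlabeled problem on a
connected, undirected PPI network: a seed set Σ of known disease genes
carries association scores `s_i ∈ (0, 1]`; all other genes are unlabeled.
The method rests on two assumptions. *Separability*: features can
distinguish disease-related from unrelated genes. *Smoothness*: genes
with similar features tend to share a label. Both are properties of the
features, which is why all four features are functions of the seed set
as a whole rather than generic centralities.

The working network is cleaned deterministically: self-loops dropped,
undirected duplicates collapsed, the largest connected component kept,
nodes ordered lexicographically. The ordering is what makes every
downstream matrix — Laplacians, similarity, transition — reproducible to
the byte.

## The four features

**Heat diffusion** solves `z'(t) = −Lz(t)`, `L = K − A`, from
`z_i(0) = s_i` on seeds and 0 elsewhere, giving `z(t) = exp(−Lt)z(0)`.
`L` has zero column sums, so the total score is conserved; score moves
at the same rate along every edge, so hubs drain quickly.

**Balanced diffusion** uses `L_b = I − K⁻¹A` instead. Each node sheds
score at unit rate regardless of degree, and the conserved quantity is
the degree-weighted sum `Σ kᵢzᵢ` (the degree vector is a left null
vector of `L_b`). The two operators have visibly different short-time
behavior, which is the regime the features use.

**Netshort** rewards genes reachable through the seed set: edge costs
`w_ij = 2/(s̃_i + s̃_j)` with `s̃_i = s_i/maxS` on seeds and
`penalization · minS/maxS` off seeds, then
`NS_i = Σ_{j≠i} 1/d_ij` over exact (Dijkstra) weighted shortest paths.
With uniform scores and `penalization = 1` every edge costs 1 and the
measure reduces to harmonic centrality — the oracle used in the tests.

**Netring** generalizes the ring decomposition to a seed *set*: ring
`R(l)` holds the nodes at minimal BFS distance `l` from any seed. Seeds
get rank `mixing · r̂_i + (1 − mixing) · mean_{j∈N(i)} r̂_j` with initial
rank `r̂_i = 1 − s_i/maxS`; a non-seed in ring `l` gets
`l + (1/k_i)(Σ_{j∈O_i} r̂_j + Σ_{j∈R_i(l−1)} (r_j − (l−1)))`. Subtracting
`l − 1` from lower-ring ranks is what makes them comparable with `r̂`:
each corrected term lies in `[0, 1]`, so every rank lands in
`[l_i, l_i + 1]` and the integer part encodes the ring. Because the rank
is processed ring by ring and depends only on `r̂` and lower-ring ranks,
it is order-independent within a ring.

The feature matrix min–max scales each column to `[0, 1]`. The raw ring
rank grows with distance from the seeds — opposite to the other three —
so it is flipped (`max − r`) before scaling by default
(`invert_netring`). How the original method maps features to `[0, 1]` is
not fully specified; min–max is this package's documented choice, and a
constant column becomes all zeros with a warning rather than an error so
degenerate fixtures still run.

## The labeling algorithm

From squared Euclidean feature distances `e_ij`, the similarity is
`w_ij = 1 − (e_ij − m)/(M − m)` off-diagonal (attaining 0 and 1), 1 on
the diagonal. Entries at or below the `q_w` empirical quantile of the
**off-diagonal** entries are zeroed — including the n known unit
diagonal entries would bias the threshold upward — and rows are
normalized: `W_n = D⁻¹W_r`. The quantile uses ECDF-linear interpolation
(`stats::quantile` type 4), the convention under which the documented
three-gene example (off-diagonal values {0, 1, 1}, `q_w = 0.5`,
threshold 0.5) works out; `q_w = 0` disables the reduction. The retained
diagonal guarantees no empty row, hence a well-defined row-stochastic
matrix.

Reliable negatives are the `|P|` genes (configurable) farthest in
Euclidean distance from the positive-centroid feature vector —
Euclidean rather than squared so tie behavior is explicit; ties break on
gene identifier. The start vector is `+1` on P, `−|P|/|RN|` on RN, 0
elsewhere, summing to zero by construction.

The restart iteration `g_r = (1 − α)W_nᵗ g_{r−1} + α g_0` (default
`α = 0.8`) contracts with ratio at most `1 − α` on the relevant
subspace; convergence is declared when the **L2 norm** of successive
differences falls below `tol = 1e−6` (the norm is not pinned down in the
original description; L2 is this package's choice, with
`max_iter = 10000` and a hard error — never a silent return — on
non-convergence). The unlabeled genes are ranked by `g_∞` descending,
ties again on identifier, and cut into LP/WN/LN blocks of sizes
`ceiling(f_LP·u)`, `min(ceiling(f_WN·u), remainder)`, remainder — a rule
that reproduces equal thirds exactly when `3 | u` and is otherwise
deterministic and documented.

Memory note: `W` is dense by construction (`n²` pairwise distances), so
the labeling stage is intended for networks up to roughly 30k nodes;
the diffusion features themselves never densify anything — the matrix
exponential acts on a vector via a trace-shifted, scaled truncated
Taylor expansion whose per-stage 1-norm is capped at 4, validated
against a dense-exponential oracle at small n.

## Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `t_heat`, `t_balanced` | 0.005 | diffusion time (dimensionless). Not pinned down by the original description; small `t` keeps scores localized so the feature encodes graded proximity to Σ rather than the flat equilibrium. |
| `penalization` | 0.5 | non-seed normalized score factor; non-seeds get `0.5 · minS/maxS`, i.e. half the weakest seed. |
| `mixing` | 0.5 | seed-rank convex-combination weight in netring; equal weight to own score and neighborhood. Unspecified originally; exposed. |
| `q_w` | 0.75 | similarity reduction quantile (off-diagonal, type 4). The exact value used originally is not stated; 0.75 keeps the strongest quartile of links. |
| `alpha` | 0.8 | restart probability, the customary value for propagation with restart. |
| `tol`, `max_iter` | 1e−6, 10000 | L2 convergence threshold and cap. |
| `rn_size` | `\|P\|` | reliable negatives; matching `\|P\|` balances the ±1 masses. |
| `fractions` | (⅓, ⅓, ⅓) | LP/WN/LN ranking split. |
| `test_fraction`, `cv` | 0.3, 5 | stratified hold-out and k-fold settings. |
| `mask_fraction`, `n_folds` | 0.2, 5 | rediscovery protocol: 20% of seeds masked per fold, five non-overlapping folds partitioning Σ. |

Masking changes only seed membership; features are always recomputed on
the original connected network, so the graph never fragments mid-protocol.

## The synthetic generator

`generate_instance()` draws a planted-partition graph: `module_size`
genes with internal edge probability `p_in = 0.3`, background pairs at
`p_out = 0.01`, defaults `n = 300`. Disconnected draws are repaired by
adding single random bridging edges (counted and reported) instead of
resampling, so the nominal edge probabilities stay honest. Module genes
split into visible seeds — scores uniform on (0.3, 1], echoing the range
typical of curated association scores — and a `hidden_fraction = 0.25`
of hidden positives emulating not-yet-curated disease genes. Everything
is a deterministic function of `rng_seed`.

What the generator emulates: a dense disease module on a sparse
background, scored seeds, held-out positives. What it does not: the
scale-free degree distribution, the size (two orders of magnitude
larger), and the ascertainment biases of real interactomes and curated
association databases. Passing tests therefore demonstrate correctness
of the algorithms and that the method recovers planted structure under
its own smoothness assumption — not field performance on real data. The
problem sizes used throughout (n = 300 study conditions; 20–50-node
graphs for oracle comparisons) were chosen as the smallest at which the
compared quantities are non-trivial.

## Numerical and degenerate-case choices

- All-equal pairwise distances (`M = m`, e.g. n = 2): similarities set
  to 1 with a warning, preserving propagation connectivity instead of
  crashing.
- Duplicate seed rows keep the **maximum** score (strongest evidence);
  seeds absent from the network are dropped with a reported count.
- Every sort is made total with the gene identifier as tie-break, so
  RN selection, rankings and labels are permutation-invariant.
- Diffusion outputs clamp negatives within `1e−12` of zero (roundoff
  from the Taylor stages) to 0.
- Association-score mode in rediscovery reports is computed on scores
  rounded to 2 decimals, smallest value on ties.
- Classifier hyperparameters are library defaults with fixed seeds; no
  conclusion in this package depends on absolute classifier scores,
  only on separable/chance-level sanity properties.

## Limitations

- The labeling stage is O(n²) in memory (dense similarity); use on full
  interactomes needs ~30k-node headroom but no more.
- Features are recomputed per masking fold; the rediscovery protocol is
  the most expensive stage (folds × (diffusion + Dijkstra + labeling)).
- Comparator discovery algorithms (DIAMOnD, MCL, plain RWR, GUILD
  variants, ToppGene) and enrichment analysis are out of scope.
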