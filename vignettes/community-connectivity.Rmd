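---
title: "Community connectivity analysis for spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community connectivity analysis for spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput spatial transcriptomics (HST) platforms such as 10x Visium
measure transcriptome-wide expression at spatially indexed capture spots.
Clustering tools assign each spot to a sub-population, but the clusters they
return are static: they say nothing about how similar two sub-populations
are to each other, or how homogeneous a sub-population is internally. In
settings such as the tumor microenvironment those quantities — the
*community connectivity structure* — are exactly what one wants: which
immune and tumor compartments interface, and which regions are internally
heterogeneous.

`spotacc` addresses this by representing an HST sample as a two-layer
spot–spot similarity network and fitting a Bayesian multi-layer stochastic
block model (MLSBM) whose connectivity matrix directly quantifies
within-community connectivity (WCC) and between-community connectivity
(BCC), with credible intervals.

## From expression and coordinates to a multi-layer graph

Layer 1 (expression similarity): counts are library-size scaled to the
median total count and `log1p`-transformed; the 2,000 most variable genes
are kept (variances are computed on the normalized values, never after
per-gene standardization, which would equalize them); genes are then
standardized and the spots embedded with PCA (default `d = 15` components —
the embedding dimension is not critical and 10–30 behave equivalently at
typical SNR); each spot is connected to its `R` nearest neighbors in the
embedding, and the digraph is symmetrized by union. Layer 2 (spatial
proximity) is the same KNN construction applied to the 2-D coordinates.

Every step is switchable (`normalize`, `scale`, `n_hvg`, `n_pcs`) because
upstream pipelines differ in which of them they have already applied.

The neighborhood size defaults to the closest odd integer to
`sqrt(N)`, ties broken downward (`default_neighbors()`). For sections of
2,000–3,000 spots this gives `R` around 45–55, i.e., roughly third- to
fourth-order neighborhoods on a hexagonal lattice, and it grows slowly with
the section size. `R` is a genuine tuning parameter: larger values share
more information across the section and smooth the inferred communities.
Union symmetrization means every node has degree *at least* `R`; mutual-KNN
(degree exactly `R` at most) would instead discard the defining property
that each spot is linked to its `R` closest neighbors. Distance ties are
broken by ascending spot index so the construction is bit-reproducible, and
duplicate coordinates are allowed (jitter-free simulated lattices produce
them; Visium spots do not).

## The model

With `A^l` the binary adjacency of layer `l = 1, …, L` (here `L = 2`),
labels `z_i ∈ {1, …, K}`, and a symmetric `K × K` connectivity matrix
`Θ`, the MLSBM assumes for every unordered pair `i < j` and layer `l`

    A_ij^l | z, Θ  ~  Bernoulli(θ_{z_i z_j})   independently.

Both layers share one set of labels and one `Θ`: an edge probability
`θ_rs` is the chance that a randomly chosen spot of community `r` shares a
nearest-neighbor edge (in either layer) with a spot of community `s`. The
diagonal entries are the WCC — low values flag internally heterogeneous
communities — and the off-diagonal entries are the BCC, which separate
closely related sub-populations from distinct ones.

Priors are conjugate and weakly informative by default:
`z_i ~ Categorical(π)`, `π ~ Dirichlet(α)` with `α_k = 1`, and
`θ_rs ~ Beta(β₁, β₂)` with `β₁ = β₂ = 1`.

### Gibbs sampler

All full conditionals are closed-form:

1. `π | z ~ Dirichlet(α_k + n_k)` with `n_k` the size of community `k`;
2. `θ_rs | z ~ Beta(β₁ + E_rs, β₂ + P_rs − E_rs)` for `r ≤ s`, where
   `E_rs` counts each unordered edge once per layer and the possible-pair
   count is `P_rs = L·n_r·n_s` off the diagonal and `L·n_r(n_r−1)/2` on
   it, consistent with the `i < j` support of the likelihood;
3. a systematic sweep redraws each `z_i` from its categorical conditional
   with `ρ_ik ∝ π_k ∏_l ∏_{j≠i} θ_{k z_j}^{A_ij^l} (1−θ_{k z_j})^{1−A_ij^l}`,
   each unordered pair entering once per layer.

The sweep is evaluated in log space from per-community neighbor counts, so
one iteration costs `O(N(K² + degree))`; the chain itself is implemented in
C++ (Rcpp). The exported R functions `update_pi()`, `update_theta()`,
`update_z()` and `canonical_relabel()` compose to exactly the same chain —
a unit test drives both through a shared RNG stream and asserts equality —
so every piece of the sampler can be inspected and tested from R.

Labels are initialized by Louvain modularity clustering of the expression
layer, adjusted to exactly `K` groups (merge the pair whose fusion costs
the least modularity; split the largest cluster by 2-means on the leading
eigenvectors of its adjacency submatrix). A good initialization mainly
shortens burn-in; the conjugate updates do the rest.

### Label switching

The likelihood is invariant under permutations of `{1, …, K}`, so an
unconstrained chain would drift between equivalent labelings and corrupt
community-specific summaries. Instead of post-hoc reshuffling, every
iteration is projected onto the canonical representative in which the first
occurrences of labels along `z` appear in increasing order; the same
permutation is applied to `π` and to the rows and columns of `Θ`. The
projection is idempotent, leaves the joint posterior exactly invariant
(asserted to `1e-12` in the tests), and makes draws from different
iterations directly comparable. Labels are estimated by the maximum a
posteriori draw: the stored post-burn iteration with the highest joint log
posterior (ties to the earliest iteration), which is a coherent single
state rather than a per-spot marginal vote.

## Connectivity summaries

`connectivity_summary()` reports `Θ̂`, the WCC vector, the BCC table, and
equal-tailed credible intervals from the per-entry chain quantiles. Two
point estimates are offered because the choice is genuinely open:

* `estimate = "map"` (default) — the `Θ` draw stored at the MAP iteration,
  self-consistent with the MAP labels. Being a single posterior draw, it
  can occasionally graze the boundary of its own tight equal-tailed
  interval;
* `estimate = "mean"` — the elementwise posterior mean, smoother and always
  interior for unimodal chains.

At typical posterior concentrations the two differ by well under 0.01.
Intervals are equal-tailed quantiles; highest-posterior-density intervals
are not implemented — at the Beta posterior concentrations involved
(possible-pair counts in the tens of thousands) the two are visually
indistinguishable. The summary also reports an estimated signal-to-noise
ratio, SNR = mean(WCC) / mean(BCC); SNR near 1 means no community
structure. Pairwise statements like "communities r,s are significantly more
connected than r,t" are operationalized as non-overlap of the 95% intervals
— a reporting convention, not a formal test.

`external_labels_acc()` runs the same analysis with `z` frozen at labels
from any external clustering tool. The `θ` posteriors are then exact
`Beta(β₁ + E_rs, β₂ + P_rs − E_rs)` distributions, so point estimates,
posterior standard deviations, and intervals are analytic — no sampling at
all. This is the recommended route for post-hoc connectivity analysis of
an existing clustering.

## The simulator and what it does (and does not) emulate

`simulate_experiment()` builds a banded tissue stand-in: `n_spots` on a
triangular lattice in a near-square rectangle (approximating hexagonal
spot geometry), split into `K = 5` contiguous vertical bands of near-equal
size — a stylized version of layered tissue such as cortical sections. The
expression layer is sampled from the SBM with the design connectivity
matrix; the spatial layer is, by default, the KNN graph of the lattice
coordinates, exactly as the package builds it for real data. Designs:

* `default` — WCC 0.3, BCC 0.1 (SNR 3);
* `setting1` — BCC of the spatially disjoint pair (1,3) and the bordering
  pair (4,5) raised to `v ∈ [0.175, 0.225]`;
* `setting2` — as setting1 with `v = 0.2`, intended for under-specified
  `K = 4` fits;
* `setting3` — WCC of communities 1–3 lowered to `v ∈ [0.2, 0.25]`.

The geometry-derived spatial layer is what produces the characteristic
spatially aware behavior: when `K` is too small or the expression SNR too
low, the model merges *bordering* bands (4,5) or splits a band rather than
merging the spatially disjoint pair (1,3).

Because the spatial layer encodes lattice adjacency rather than draws from
`Θ`, the pooled `Θ̂` under this design estimates the average of the
expression-layer `Θ` and the spatial block densities — by design, not by
error. Calibration checks of `Θ̂` against the generating matrix therefore
use `spatial_layer = "sbm"`, which samples both layers from `Θ` and makes
the model correctly specified; under that design the package recovers all
15 entries of the default `Θ` to well under 0.01 at `n = 800`.

Default problem sizes are a deliberate desk-scale choice: 800 spots
(`R = 29` by the heuristic), 2,000 iterations with 1,000 burn-in. A full
fit takes a few seconds, so the validation suite can afford dozens of
independent replicates.

What passing these simulations does **not** show about real data: the
simulator draws the expression network directly from the SBM, so it has no
count noise, no library-size or batch effects, no irregular tissue
geometry, unequal or non-contiguous community sizes, or degree
heterogeneity (peripheral spots in real sections have fewer close
neighbors; a degree-corrected extension would be needed to capture hub
structure). Real-data SNRs are typically much higher (near 10) than the
simulated 1.75–3 range, which was chosen to probe the hard regime.

## Numerical choices and degenerate inputs

* `θ` is clamped to `[1e-12, 1 − 1e-12]` inside all likelihood
  evaluations, so log terms are always finite, including under saturated
  or empty graphs.
* Empty communities are legal mid-chain: the Dirichlet and Beta updates
  remain proper (the Beta falls back to its prior when `P_rs = 0`), and if
  the MAP draw itself uses fewer than `K` labels the package warns rather
  than failing.
* KNN distance ties and categorical-draw boundaries are index-ordered, and
  all randomness flows from one explicitly required seed (there is no
  silent default seed), so chains are bit-reproducible.
* Readers validate rather than repair: asymmetric, self-looped, duplicate,
  or out-of-range edge-list rows are errors.
* The `pair_counts()` convention counts each unordered pair once per
  layer. The alternative convention that doubles the off-diagonal
  possible-pair count merely rescales the Beta posterior's effective
  sample size; it leaves the label posterior essentially unchanged in
  high-SNR regimes but would mis-calibrate `Θ̂` against the generative
  model, so the single-count form consistent with the `i < j` likelihood
  support is used throughout.

## Known limitations

* No degree correction, data-adaptive layer weights, or layer-specific
  community structure; both layers share `z` and `Θ`.
* Single-site Gibbs sweeps move one label at a time, so at very low SNR
  the chain can be slow to traverse between partition modes; the Louvain
  initialization mitigates but does not eliminate this.
* The joint credible statement "all `K(K+1)/2` intervals simultaneously
  cover" is *not* controlled at the per-entry level: fifteen simultaneous
  marginal 95% intervals jointly cover roughly `0.95^15 ≈ 46%` of the
  time. Users needing simultaneous coverage should Bonferroni-adjust
  `level`.
* Dense `N × N` distance and adjacency intermediates cap the practical
  size at a few thousand spots — comfortable for Visium sections, not for
  imaging platforms with 10⁵–10⁶ cells without down-sampling.
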