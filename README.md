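# spotacc

Community connectivity analysis for high-throughput spatial
transcriptomics (HST).

Clustering tools for Visium-style data assign each capture spot to a
sub-population but say nothing about how those sub-populations relate:
which pairs interface tightly, and which communities are internally
heterogeneous. `spotacc` quantifies exactly that. It represents a tissue
section as a two-layer spot–spot similarity network — one layer built from
gene expression (highly variable genes → PCA → K-nearest neighbors), one
from the spatial coordinates — and fits a Bayesian multi-layer stochastic
block model (MLSBM) by Gibbs sampling:

    A_ij^l | z, Θ  ~  Bernoulli(θ_{z_i z_j}),   i < j,  l = 1, …, L

with labels `z_i ∈ {1, …, K}`, a symmetric `K × K` connectivity matrix
`Θ`, and conjugate priors `π ~ Dirichlet(α)`, `θ_rs ~ Beta(β₁, β₂)`
(defaults `α = 1`, `β₁ = β₂ = 1`). The diagonal of `Θ̂` is the
within-community connectivity (WCC, a homogeneity measure), the
off-diagonal the between-community connectivity (BCC, a relatedness
measure); both come with equal-tailed credible intervals. Label switching
is blocked inside the sampler by projecting every iteration onto the
canonical labeling (first occurrences in increasing order), and labels are
estimated by the maximum a posteriori post-burn draw.

The intended users are analysts of Visium / CosMx-scale experiments who
want a model-based relatedness analysis of spot clusters — either fitted
end to end, or post hoc on labels from any other clustering tool
(`external_labels_acc()`, fully analytic).

See `vignette("community-connectivity")` for the model, its assumptions,
and all design choices.

## Worked example

Simulate a banded 800-spot section (five contiguous communities, within-
connectivity 0.3, between-connectivity 0.1 — SNR 3), fit the model, and
summarize connectivity:

```r
library(spotacc)

sim <- simulate_experiment("default", n_spots = 800, seed = 3)
print(sim)
#> sim_truth: default, 800 spots, 5 bands, R = 29, seed 3
#>   spatial layer: knn; true SNR = 3.00

fit <- run_gibbs(sim$graph, K = 5, n_iter = 2000, burn = 1000, seed = 3)
z <- map_labels(fit)
ari(z, sim$z_true)
#> [1] 1

summary <- connectivity_summary(fit)
print(summary)
#> acc_summary (posterior (map)): K = 5, level = 0.95
#> within-community connectivity (WCC):
#> [1] 0.238 0.220 0.223 0.220 0.244
#> between-community connectivity (BCC):
#>  r s estimate lower upper
#>  1 2    0.063 0.061 0.065
#>  1 3    0.051 0.048 0.052
#>  1 4    0.050 0.049 0.053
#>  1 5    0.049 0.048 0.051
#>  2 3    0.062 0.060 0.064
#>  2 4    0.050 0.048 0.052
#>  2 5    0.050 0.048 0.052
#>  3 4    0.063 0.061 0.065
#>  3 5    0.049 0.048 0.051
#>  4 5    0.062 0.060 0.064
#> estimated SNR (mean WCC / mean BCC): 4.17
```

The model recovers all five bands exactly (`ari = 1`). The `Θ̂` entries
pool both layers: each WCC ≈ (0.3 + spatial lattice density)/2 ≈ 0.23,
and the elevated BCC values (≈ 0.06) are precisely the spatially
*bordering* band pairs (1,2), (2,3), (3,4), (4,5), which share spatial
edges along their boundary — the spatial layer is visible in the estimate,
by construction. Fitting the fully generative variant
(`spatial_layer = "sbm"`) instead recovers the generating matrix itself
(all entries within < 0.01 of truth and estimated SNR ≈ 3).

For real data, replace the simulation with

```r
counts <- read_expression("filtered_matrix.mtx")   # or dense CSV/TSV
coords <- read_coords("tissue_positions.csv")      # Visium or id,x,y CSV
graph  <- build_multilayer(counts, coords)          # R defaults to ~sqrt(N)
fit    <- run_gibbs(graph, K = 5, n_iter = 2000, burn = 1000, seed = 1)
```

A thin command-line front end with `fit`, `simulate`, and `acc`
subcommands is installed at `system.file("cli/spotacc.R",
package = "spotacc")`.

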