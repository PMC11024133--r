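# spotdecon

Domain-aware, reference-based cell-type deconvolution for
sequencing-based spatial transcriptomics.

Each capture spot of a Visium-style assay measures a mixture of cells.
`spotdecon` estimates the cell-type composition of every spot from an
annotated scRNA-seq reference, exploiting the structure of tissue:
spots in the same **spatial domain** share a common *set* of cell types,
while the *proportions* vary spot by spot. It is written for
computational biologists analysing spatial data who already have (or can
cluster) domain labels and a labelled single-cell reference.

## Method

Three stages per tissue section:

1. **Domains.** Import labels from any spatial-domain caller
   (`spot_id,domain` CSV), or use the built-in fallback clusterer
   (PCA on expression + scaled coordinates + k-means + one round of
   neighbour smoothing).
2. **Cell-type selection.** Per spot, a Lasso fit against the
   gene-by-cell-type signature matrix:

   $$\sum_{i=1}^{M}\Big(y_i-\sum_{j=1}^{K}\beta_j x_{ij}\Big)^2
     +\lambda\sum_{j=1}^{K}|\beta_j|,$$

   with λ chosen by 10-fold cross-validation over genes. The
   spot-by-type coefficient matrix is binarised by adaptive thresholding
   (local-mean filtering via FFT 2D convolution; an entry is selected
   when its coefficient strictly exceeds the local mean) and aggregated:
   type *j* enters the domain set $S_d$ when it is selected in ≥ τ of
   the domain's spots (default τ = 0.25).
3. **Proportions.** Per spot, least-absolute-deviation regression on the
   probability simplex restricted to $S_d$:

   $$\hat p=\arg\min_{p}\sum_{i=1}^{M}\Big|y_i-\sum_{j\in S}p_j x_{ij}\Big|
     \quad\text{s.t. } p_j\ge 0,\ \textstyle\sum_{j\in S}p_j=1,$$

   solved exactly via the residual-splitting linear program (an ADMM /
   augmented-Lagrangian backend is also provided). The L1 loss makes the
   fit robust to outlying genes.

The signature matrix $x_{ij}$ is the per-type mean of
library-size-scaled scRNA-seq expression over feature genes (shared with
the spatial data, user-supplied markers, or one-vs-rest Wilcoxon
rank-sum markers with Benjamini–Hochberg adjustment).

A Dirichlet pseudo-spot simulator with ground truth
(`simulate_reference()`, `make_domain_layout()`,
`simulate_spatial_dataset()`) and benchmarking metrics (mAD, RMSE,
Pearson R, per-domain TPR/FPR, colocalization) make the whole pipeline
testable offline. See `vignettes/spotdecon-methods.Rmd` for the full
model description, parameter defaults and limitations.

## Worked example

```r
library(spotdecon)

sc     <- simulate_reference(seed = 7)       # toy annotated scRNA-seq, K = 6
layout <- make_domain_layout(8, 8, 3)        # 64 spots, 3 banded domains
sim    <- simulate_spatial_dataset(sc, layout, benchmark_alpha(6, 3),
                                   cells_per_spot = 50, seed = 11)

fit <- run_pipeline(sim$spatial, sc, domains = sim$truth$layout,
                    config = pipeline_config(seed = 42))
fit
#> <spot_deconvolution> 64 spots, 6 cell types, 3 domains
#>   feature genes: 180; median LAD objective: 0.02158
#>   domain 0: type1, type4, type6
#>   domain 1: type2, type4, type5
#>   domain 2: type3, type5, type6

evaluate_deconvolution(fit$proportions, sim$truth, fit$selection)
#> <evaluation_report>
#>   overall: mAD 0.00272, RMSE 0.004591, R 0.9999
#>   selection: mean TPR 1, mean FPR 0
```

The run recovered exactly the dominant + minor type sets planted in each
domain (TPR 1, FPR 0), and the estimated proportions track the Dirichlet
ground truth to a mean absolute deviation of 0.003. Results are tibbles
away via broom-style verbs:

```r
tidy(fit)      # spot_id, cell_type, proportion, domain — one row per pair
glance(fit)    # one-row run summary (spots, types, feature genes, ...)
autoplot(fit, coords = sim$spatial$coords)   # spatial proportion maps
plot_colocalization(fit$proportions)          # pairwise Pearson heatmap
```

Real data enter through `load_spatial()` (Matrix Market triplet
directory or dense CSV, plus a coordinate table), `load_single_cell()`,
and `load_domain_labels()`; results leave through `write_proportions()`
and `write_run_log()`. A thin command-line front end with `run`,
`simulate` and `evaluate` subcommands is installed under
`inst/cli/spotdecon`.

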