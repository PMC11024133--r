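---
title: "Methods: domain-aware deconvolution of spatial transcriptomics spots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-aware deconvolution of spatial transcriptomics spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

## The problem

Sequencing-based spatial transcriptomics (e.g. 10x Visium) measures the
whole transcriptome at each capture spot, but every spot contains a small
mixture of cells. Downstream analyses — differential expression across
regions, colocalization, tissue architecture — are confounded unless the
cell-type composition of each spot is known. `spotdecon` estimates that
composition from an annotated scRNA-seq reference, with one structural
assumption that distinguishes it from bulk-style deconvolution: **cell
types are not uniformly present across a tissue**. Spots belonging to the
same spatial domain (a region coherent in expression and histology) share
a common *set* of cell types, while the *proportions* of those types vary
from spot to spot.

The pipeline has three stages:

1. **Spatial domains.** A partition of spots into domains is either
   imported from a dedicated spatial-domain caller (the supported path —
   any `spot_id,domain` CSV works) or produced by a simple built-in
   fallback clusterer. Graph-convolutional domain detection is explicitly
   out of scope here; the contract is "domains in, proportions out".
2. **Per-domain cell-type selection.** For every spot, a Lasso regression
   of the spot's expression on the signature matrix shrinks the
   coefficients of absent cell types to zero; the spot-by-type coefficient
   matrix is binarised by adaptive thresholding and aggregated into a
   per-domain set \(S_d\).
3. **Proportion estimation.** For every spot, proportions over
   \(S_{d}\) are fitted by least-absolute-deviation (LAD) regression on
   the probability simplex.

## Reference construction

From raw scRNA-seq counts with cell-type labels:

* genes with zero total count are removed, and unwanted annotation
  categories can be dropped (`keep_types`);
* each cell is scaled by its library size (the column then sums to 1);
* one-vs-rest marker genes are detected per cell type with a two-sided
  Wilcoxon rank-sum test on the scaled expression, Benjamini–Hochberg
  adjustment within cell type, defaults `max_adj_p = 0.05` and
  `min_lfc = 0.25` on the natural-log fold change
  \(\ln(\bar x_{in}+\varepsilon) - \ln(\bar x_{out}+\varepsilon)\),
  \(\varepsilon = 10^{-9}\). A `pairwise = TRUE` mode keeps a gene if it
  is significant in any pairwise type comparison instead;
* feature genes are those satisfying *any* of: shared with the spatial
  data, user-supplied marker, detected marker — then intersected with the
  spatial gene set so every fit is well-posed;
* the signature entry \(x_{ij}\) is the mean scaled expression of gene
  \(i\) over cells of type \(j\) (pooled across samples by default;
  `per_sample_mean = TRUE` averages per-sample means instead). Per-gene
  cross-sample variance is reported for diagnostics but does not weight
  the fits, which are deliberately unweighted.

The rank-sum test uses exact enumeration when the pooled sample size is at
most 12 without ties, and the tie- and continuity-corrected normal
approximation otherwise.

## Cell-type selection

Per spot, with \(y_i\) the spot's expression for feature gene \(i\) and
\(x_{ij}\) the signature, the Lasso objective is

\[
\sum_{i=1}^{M}\Big(y_i-\sum_{j=1}^{K}\beta_j x_{ij}\Big)^2
+\lambda\sum_{j=1}^{K}\lvert\beta_j\rvert ,
\]

minimised exactly in this parameterisation (no intercept, no
standardisation, no \(1/2M\) factor) by cyclic coordinate descent.
\(\lambda\) is chosen by 10-fold cross-validation with *genes* as the
observations: the fold assignment is one seeded shuffle of the genes,
shared by all spots, and the score is mean squared prediction error on
held-out genes. The default grid is 50 log-spaced values from
\(\lambda_{\max}=2\max_j\lvert X^\top y\rvert_j\) (the smallest penalty
with an all-zero solution) down to \(10^{-4}\lambda_{\max}\).

The spot-by-type coefficient matrix is then binarised by **adaptive
thresholding**: coefficients are clipped at zero (negative abundance is
meaningless), smoothed by a local-mean 2D convolution computed via the
FFT, and an entry becomes 1 exactly when the coefficient strictly exceeds
its local mean. Rows are ordered by (domain, array row, array col) so the
convolution's row neighbourhood is spatially meaningful. Finally
\(S_d = \{j:\) type \(j\) is selected in at least a fraction
\(\tau\) of domain \(d\)'s spots\(\}\), default \(\tau = 0.25\); an empty
set falls back to the type with the largest mean coefficient in the
domain (with a warning).

Numerical choices worth knowing:

* **Window default 15×3** (spots × types). The two flanking cell-type
  columns enter each coefficient's local mean; on the synthetic benchmark
  this suppresses the small spurious coefficients of absent types (which
  would otherwise beat the near-zero local mean of their own column
  roughly half the time) while leaving genuine minor types intact. The
  cost is that the *binary matrix* is not exactly invariant to the
  arbitrary ordering of cell-type columns; with a width-1 window
  (`threshold_window = c(15, 1)`) selection is provably column-order
  invariant, and that configuration is what the invariance property test
  uses. Both dimensions are config knobs and are clamped (with a warning)
  to the matrix size.
* **Boundary padding** is half-sample symmetric (edge values repeated),
  applied identically in the FFT path and in the brute-force convolution
  the tests compare against.
* **Tie rule**: strictly-greater comparison with a numerical guard of
  \(10^{-9}(1+\max\beta)\), so FFT round-off cannot promote exact ties; a
  constant coefficient matrix binarises to all zeros.
* Spot expression over the feature genes is scaled to sum 1, and
  signature columns are likewise scaled to sum 1, before both the Lasso
  and the LAD fits (`normalization_mode = "spot"`, the default). The
  column rescale matters: gene filtering removes a different fraction of
  each cell type's library mass, and without it the simplex fit is biased
  toward types whose profiles keep more mass on the feature genes. With
  it, Lasso coefficients are directly interpretable as approximate
  proportions. `normalization_mode = "none"` fits raw values.

## Proportion estimation

Per spot, with \(S\) the domain's selected set,

\[
\hat p=\underset{p}{\arg\min}\ \sum_{i=1}^{M}\Big\lvert\,
y_i-\sum_{j\in S}p_j x_{ij}\Big\rvert
\quad\text{s.t.}\quad p_j\ge 0,\ \sum_{j\in S}p_j=1 .
\]

The absolute-deviation loss is deliberately robust: a handful of outlying
genes moves the fit far less than under squared loss (the test suite
demonstrates this against a least-squares-on-simplex baseline). The
problem is convex — splitting each residual into positive and negative
parts turns it into the linear program
\(\min \sum_i (r^+_i + r^-_i)\) s.t. \(Xp + r^+ - r^- = y\),
\(\mathbf 1^\top p = 1\), all variables \(\ge 0\) — so the default
backend solves that LP exactly with the two-phase simplex method and the
optimum is certifiable. A second backend runs ADMM (an
augmented-Lagrangian / alternating-direction scheme on the same
constraints: soft-thresholding for the residual block, projected gradient
onto the simplex for \(p\)); both meet the same contract and the tests
compare both against an independent LP implementation. Cell types outside
\(S\) get proportion exactly 0 by construction. Degenerate LPs can have
multiple optimal vertices; tests therefore compare objectives, not
coefficient vectors, whenever the design is column-degenerate. An
all-zero spot yields the uniform distribution over \(S\) with a warning.

By default all feature genes enter the LAD fit; restricting to the
detected markers of the selected types is a documented alternative but
not the default, because the shared genes stabilise the simplex scale.

## The fallback domain clusterer

log1p of spot-normalised expression → top 50 principal components →
z-scaled array coordinates (and mean spot RGB, if present) appended with
weight 1 → k-means with \(D\) centres (10 seeded starts) → one round of
spatial smoothing where each spot takes the majority label among its 6
nearest neighbours, ties keeping the spot's own label. \(D\) must be
user-supplied; there is no automatic selection rule. This is a deliberately
simple clusterer so the pipeline runs standalone — for real tissue use a
dedicated spatial-domain caller and import its labels.

## The synthetic-data generator

The generator emulates the standard pseudo-spot construction used to
benchmark reference-based deconvolution:

1. spots sit on an integer grid, with contiguous horizontal bands of rows
   forming domains;
2. each spot draws its true proportions from the Dirichlet distribution
   of its domain, restricted to the types with positive concentration —
   the draw itself is the recorded ground truth;
3. `cells_per_spot` cells are allocated to types by largest-remainder
   rounding of the draw (so allocations always sum exactly), sampled with
   replacement from the reference, and their raw counts are summed into
   the spot's column;
4. optional noise multiplies every count by an independent
   lognormal\((0,\sigma)\) factor and rounds to the nearest integer, at
   preset levels \(\sigma\in\{0, 0.2, 0.5, 1.0\}\).

Default concentrations give each domain one dominant type
(\(\alpha = 5\)) and minor types at \(\alpha = 1\), absent types 0; with
`benchmark_alpha(K, D)` types \(1..D\) are the dominants and each
remaining type is a minor of two consecutive domains. `cells_per_spot`
defaults to 10, a realistic spot occupancy for Visium-scale arrays; the
benchmark runs use 50 to reduce sampling noise.

The bundled toy reference (`simulate_reference()`) draws block-structured
Poisson counts: 25 private marker genes per type plus 30 housekeeping
genes, 60 cells per type over two pseudo-samples, equal expected library
size per type. Equal library sizes make cell-count proportions and
expression proportions coincide, so recovered proportions are directly
comparable to the Dirichlet truth. This is exactly what real tissue does
*not* guarantee: real cell types differ in RNA content, scRNA-seq has
dropout and overdispersion the Poisson model lacks, and real domains have
ragged boundaries. Passing tests on this generator therefore demonstrate
correctness of the machinery and robustness ordering under noise — not
field accuracy on any particular tissue.

## Benchmark problem sizes

The standard benchmark used by the acceptance checks is a 20×20 grid
(400 spots), 3 banded domains, K = 6 types, 50 cells per spot,
noise-free; the noise sweep uses 10×10 grids (100 spots) at
\(\sigma\in\{0,0.2,0.5\}\) with three simulation seeds per level; the
determinism check uses a 6×6 grid. These sizes were chosen so the full
suite exercises every stage at meaningful scale while staying quick to
run on a laptop.

## Known limitations

* Rare cell types (small \(\alpha\), low counts) are the hardest case:
  shrinkage can drop them from \(S_d\) entirely, and their proportions
  are underestimated — a limitation shared by reference-based
  deconvolution generally.
* One scRNA-seq reference at a time; no batch integration of multiple
  references, no ambient-RNA or doublet handling.
* The domain aggregation rule (\(\tau\)) and threshold window are
  pragmatic defaults, exposed in `pipeline_config()`; there is no
  data-driven selection rule for them.
* Degenerate signatures (nearly collinear columns) give non-unique LAD
  optima; the solver's deterministic pivoting picks one vertex
  reproducibly, but the reported proportions for collinear types should
  not be over-interpreted.
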