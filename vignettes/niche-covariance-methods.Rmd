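---
title: "Niche covariance, AOT geometry and cross-modality integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche covariance, AOT geometry and cross-modality integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covetenvi)
```

# The model

## COVET: niches as shifted covariance matrices

A cell's microenvironment is summarized by the gene–gene covariance of its
niche — its $k$ spatially nearest cells (default $k = 8$, the immediate
neighbourhood in most segmented tissues; a radius mode is available for
tissues with very uneven density). For niche matrix $E_i \in \mathbb R^{k
\times g}$ the usual covariance would centre each niche at its own mean,
which destroys comparability across niches. COVET instead centres every
niche at the same dataset-wide mean $\bar X$:

$$\Sigma_i = \mathrm{ShiftCov}(E_i) = \tfrac1k (E_i - \bar X)^\top (E_i - \bar X).$$

This "shifted" covariance remains symmetric positive semi-definite (it is a
Gram matrix), retains the niche's mean shift as a rank-one component, and
makes all $\Sigma_i$ directly comparable because they share a reference.
When the reference equals the niche's own mean, the formula reduces to the
classical population covariance — `shifted_covariance()` is tested for both
identities.

## Comparing niches: Fréchet and AOT distances

Zero-mean Gaussians with covariances $\Sigma_i, \Sigma_j$ have the
closed-form squared 2-Wasserstein (optimal transport) distance

$$\Delta_{\text{Fréchet}} = \mathrm{Tr}(\Sigma_i) + \mathrm{Tr}(\Sigma_j)
 - 2\,\mathrm{Tr}\!\left(\sqrt{\Sigma_i\Sigma_j}\right),$$

which needs one matrix square root per *pair*. Swapping the root and the
product gives the approximate optimal transport (AOT) distance

$$\Delta_{\text{AOT}} = \mathrm{Tr}(\Sigma_i) + \mathrm{Tr}(\Sigma_j)
 - 2\,\mathrm{Tr}\!\left(\sqrt{\Sigma_i}\sqrt{\Sigma_j}\right)
 = \left\lVert \sqrt{\Sigma_i} - \sqrt{\Sigma_j} \right\rVert_2^2,$$

exactly equal to the Fréchet distance whenever the two matrices commute.
The second identity is the workhorse: after one symmetric PSD square root
per cell (`matrix_sqrt_psd()`, eigendecomposition with square-rooted
eigenvalues), all pairwise distances are plain squared Euclidean distances
between flattened matrices, so any Euclidean algorithm (k-NN, k-means,
diffusion maps) operates directly in AOT geometry. Distances are kept
squared throughout; downstream k-NN ranks are invariant to the monotone
square root.

`pairwise_aot()` uses the flatten-and-`dist()` path and is tested
bit-for-bit against the per-pair trace formula; the test suite also checks
rank agreement (Spearman > 0.9) between AOT and the brute-force Fréchet
oracle on a 200-matrix Wishart ensemble. The Bhattacharyya distance (the
zero-mean Gaussian convention
$\tfrac12\ln\{\det(\tfrac{\Sigma_1+\Sigma_2}{2})/\sqrt{\det\Sigma_1\det\Sigma_2}\}$)
is implemented only as a benchmarking reference.

Group summaries use the AOT mean, $(\tfrac1n\sum_i\sqrt{\Sigma_i})^2$
(`covet_mean()`).

## MSSI: multiscale similarity on a cell graph

`mssi()` adapts multiscale SSIM from raster images to segmented cells. The
image pyramid becomes a graph pyramid: the k-NN graph of cell positions
(default $k = 8$, mirroring the niche default) is coarsened four times by a
factor of two, and the luminance/contrast/structure terms

$$l = \frac{2\mu_x\mu_y + C_1}{\mu_x^2+\mu_y^2+C_1},\quad
  c = \frac{2\sigma_x\sigma_y + C_2}{\sigma_x^2+\sigma_y^2+C_2},\quad
  s = \frac{\sigma_{xy} + C_2/2}{\sigma_x\sigma_y + C_2/2}$$

with $C_1 = (0.01M)^2$, $C_2 = (0.03M)^2$ and $M$ the joint maximum of the
two pooled signals, are combined as
$\mathrm{MSSI} = l_5^{\alpha_5}\prod_{s=1}^4 c_s^{\alpha_s}s_s^{\alpha_s}$
with the standard MS-SSIM weights
$\alpha = (0.0448, 0.2856, 0.3001, 0.2363, 0.1333)$. Signals are scaled to
$[0,1]$ by their own maxima once, at the original scale, and never
re-normalized at coarser scales; $M$ is recomputed per scale. Negative
structure terms are clipped to zero, so anti-correlation at any scale
annihilates the whole product: the index lives on $[0, 1]$, is exactly 1
for identical profiles and exactly 0 for profiles anti-correlated at the
finest scale.

Two deliberate choices:

* **Luminance constant.** Some descriptions of this index print the
  luminance denominator constant as $0.01/M$ rather than $(0.01M)^2$. With
  the former, identical signals no longer score exactly 1 and the $[0,1]$
  range is not guaranteed — properties the index is explicitly meant to
  have. We therefore default to the standard SSIM constant and expose the
  as-printed variant through `luminance = "as-printed"` for cross-checks.
* **Coarsening operator.** Any coarsening that "pools nodes by their
  connectivity" fits the contract; we use deterministic greedy heavy-edge
  contraction: edges are processed in decreasing weight order (ties broken
  by node index) and contracted until the node count halves. Edge weights
  accumulate across levels, pooling is the uniform average of merged nodes
  (rows of each operator are convex weights, so constant signals are fixed
  points), and nodes in disconnected components are never merged.
  Degenerate all-zero signal pairs at a scale contribute factors of 1, the
  limit of identical signals.

## ENVI: one latent space for two modalities

ENVI is a conditional variational autoencoder over both datasets. The
encoder sees the shared (imaged) gene panel plus one auxiliary binary
neuron — 0 for spatial cells, 1 for dissociated cells — and returns a
diagonal Gaussian posterior $(\mu_l, \sigma_l)$ over a latent vector;
samples use the reparameterization $l = \mu_l + \varepsilon\sigma_l$. Two
decoders read the latent:

* the **expression decoder** (conditioned on the same auxiliary neuron)
  parameterizes a negative binomial over the *full* single-cell gene scope
  — $r$ through a softplus, $p$ through a sigmoid, so the single-cell term
  covers genes the encoder never saw — and a Poisson rate over the imaged
  panel through a softplus on the first $g_{st}$ output neurons, which are
  the only output neurons shared between modalities;
* the **environment decoder** outputs the $g_{st}(g_{st}+1)/2$ entries of a
  lower-triangular factor $L$; its Gramian $LL^\top$ is the mean of an
  isotropic Gaussian over COVET square roots, whose log-likelihood is
  $-\tfrac12\lVert\sqrt\Sigma - LL^\top\rVert_2^2$ — i.e. half the AOT
  distance, so reconstruction error and niche geometry coincide. Square
  roots of all spatial COVETs are computed once before training.

Training maximizes the ELBO
$\ln NB(X_{sc}\mid r,p) + \ln \mathrm{Pois}(X_{st}\mid\lambda)
 + \ln N(\sqrt{\Sigma_{st}}\mid LL^\top, I) - \beta D_{KL}$,
with each reconstruction term averaged per cell within its modality so the
balance is independent of dataset sizes. Normal and zero-inflated negative
binomial heads are also implemented and selectable per modality; all four
heads pass brute-force normalization checks, and the ELBO is verified
term-by-term against an independent recomputation from the exported
log-pmfs on a fixed batch.

Defaults follow the reference recipe: latent 512, three hidden layers of
1,024 ReLU units per network, $\beta = 0.3$ ($\beta = 1.0$ when the
combined data have fewer than 10,000 cells and the user did not set
$\beta$), Adam for $2^{14}$ steps at learning rate $10^{-3}$ dropping to
$10^{-4}$ in the final quarter, batches of 1,024 split evenly between
modalities (drawn with replacement from each), and the single-cell scope
restricted to the union of the spatial panel with the 2,048 most variable
remaining genes (variance of log1p counts — a simple, deterministic
criterion). The training-step count is stored in the configuration and can
be set freely. Networks and gradients are implemented directly in R as
dense matrix operations with analytic derivatives and Glorot
initialization under a fixed seed.

Two inference paths reuse the trained networks with deterministic
posterior-mean latents (a sampling flag exists):

* **imputation** encodes a spatial cell (flag 0) and decodes with the
  single-cell flag 1, returning the negative binomial expectation
  $r(1-p)/p$ for every gene in the single-cell scope, including unimaged
  ones;
* **COVET inference** applies the environment decoder to single-cell
  latents; outputs are Gramians, hence symmetric PSD square roots directly
  comparable to measured ones under AOT.

Encoder inputs default to log1p counts, and spatial COVETs used as
training targets are computed on log1p expression by default (both
config-exposed): the Gaussian environment head is better behaved when the
targets do not span count scales.

## Downstream niche analysis

* **Diffusion components** (`diffusion_components()`): k-NN graph (default
  30) on the flattened COVET square roots, adaptive Gaussian kernel,
  symmetrization by averaging, eigenvectors of $D^{-1}A$ ordered by
  eigenvalue magnitude with the trivial constant eigenvector dropped. The
  exact kernel form is our choice: per-point bandwidth equal to the
  distance to the `adaptive_k`-th neighbour (default 10) times a global
  `width` scale (default 1). Eigenvector signs are arbitrary; we fix them
  to correlate non-negatively with the first input feature. On
  disconnected graphs the components are computed on the largest connected
  component with a warning.
* **AOT k-NN label transfer** (default $k = 5$): majority vote, ties broken
  by the smallest summed distance, then alphabetically — fully
  deterministic.
* **Niche composition**: counts of each cell type among a cell's 8 niche
  neighbours (rows sum to 8), extended to query cells by averaging the
  compositions of their `k_reg = 5` AOT-nearest spatial cells.
* **Expression–environment concordance**: k-means (default $k = 5$) on log
  expression and, independently, on flattened COVET roots, each restarted
  10 times with seeds `seed..seed+9`; the mean adjusted Rand index over all
  100 pairings is reported. Restart variability is part of the statistic.
* **Batch ASW**: the latent is compressed to its top 10 principal
  components; within each cell type spanning both modalities the modality
  silhouette is computed and each cell contributes $1 - |s_i|$; per-type
  means are averaged. 1 means perfect mixing.

# The synthetic tissue generator

`simulate_tissue()` builds the statistical structures the methods exploit,
and nothing else. Cells sit on a jittered grid; zones are bands along y; a
gradient runs along x (orthogonal, so the two factors never alias). Genes
fall into blocks: per-type markers (+2 log-units), noisy ligands, a
receiver block whose log-mean follows the standardized mean ligand signal
of the cell's 8 spatial neighbours with a zone-dependent coefficient, a
gradient block, and unstructured housekeeping/extra genes. Spatial counts
are Poisson; `dissociate()` resamples all genes with negative binomial
noise (default size 2), log-normal library factors (sd 0.3) and 10%
dropout, discarding coordinates — the modality gap the integration model
has to bridge.

Design points worth stating explicitly:

* **Coupling is the only zone signal.** Zone-specific ligand enrichment and
  ligand→receiver niche coupling both scale with `coupling_strength`, so at
  coupling 0 zones are statistically identical (cross-tissue niche
  classifiers operate at chance — a property test), while the `archetypes`
  preset (coupling 2.5, two zones enriched for different ligand pairs)
  yields two niche programs of equal magnitude but different orientation.
  Equal magnitude matters: inferred COVETs are smoother than measured ones
  (a conditional mean cannot reproduce sampling noise), and archetypes that
  differed only in amplitude would bias nearest-neighbour votes toward the
  larger class.
* **Gradient genes are staggered sigmoids.** Linear ramps all crossing the
  global mean at the tissue midline make every COVET entry an even function
  of position — the axis folds onto itself and no embedding can recover its
  sign. Sigmoidal domains with staggered activation centres (the shape of
  axial patterning series) give each position a distinct niche signature.
  The `gradient` preset uses a homogeneous cell population with a strong
  (4 log-unit) gradient so that the planted axis dominates COVET variation;
  its first diffusion component then rank-correlates with the axis.
* Grid-with-jitter geometry keeps k-NN well conditioned and tie-free.

What the generator does *not* emulate: segmentation errors, spatial
domains with curved geometry, cell-type-dependent capture efficiency,
batch effects within a modality, or realistic transcriptome-wide
co-expression modules. Passing tests on this generator show the machinery
is correct and self-consistent, not that any biological claim transfers to
real tissue.

# Numerical choices

* PSD tolerance: eigenvalues below $-10^{-8}$ *relative to the largest
  eigenvalue magnitude* (floored at 1) are an error; small negatives above
  the threshold are clipped to zero before square roots. A relative
  threshold treats count-scale and log-scale matrices alike.
* Neighbour ties anywhere (niche index, label transfer, coarsening) break
  by ascending index for cross-platform determinism.
* The encoder's log-variance output is clamped to $[-8, 4]$; likelihood
  parameters get floors ($p$ and $\pi$ in $[10^{-6}, 1-10^{-6}]$, rates
  $\geq 10^{-6}$) to keep log-pmfs finite.
* Empty radius-mode niches are flagged and excluded from distance
  matrices rather than zero-filled; a zero matrix would silently pose as a
  real niche.
* k-means restarts and all simulation seeds are explicit function
  arguments; the package never reads global RNG state implicitly except
  where documented.

# Problem sizes in the tests and acceptance script

The suite exercises the stochastic claims at sizes a laptop CPU handles in
seconds per block: tissues of 256–576 cells with 30 genes (20 imaged),
ENVI configurations of 2 hidden layers (96–128 units), latent 16–24,
800–1,000 training steps and batches of 128–256, Wishart ensembles of 200
8×8 matrices, and 1,000-pair property sweeps. These sizes were chosen so
that effect sizes planted by the generator are comfortably detectable;
they are stated here so results can be reproduced exactly with
`scripts/acceptance.R`.

A known stochastic edge case: on a small fraction of gradient-preset
realizations the two leading non-trivial eigenvalues of the diffusion
operator are nearly degenerate and the planted axis splits between the
first two components, lowering the DC1 correlation. This is a property of
diffusion maps near eigenvalue crossings, not of the COVET construction;
the axis is still recovered by the leading pair.

# Limitations

* The CVAE runs on dense in-memory matrices; it is sized for
  tens-of-thousands of cells and a few thousand genes, not atlas-scale
  data, and there is no GPU path.
* Disk formats are delimited text and MatrixMarket; no HDF5 container.
* The Bhattacharyya implementation assumes zero-mean Gaussians and is a
  benchmarking oracle, not a recommended niche metric.
* Comparator integration methods are out of scope; the evaluation harness
  (`evaluate_imputation()`) accepts any method's imputed matrix.
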