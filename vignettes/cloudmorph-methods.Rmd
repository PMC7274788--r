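---
title: "Point-cloud morphometry with cloudmorph: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-cloud morphometry with cloudmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudmorph)
```

## The problem

Quantifying the shapes and subcellular organization of thousands of cells in
an intact, developing tissue requires a representation that is (i) landmark
free — epithelial and mesenchymal cells offer no homologous anatomical
points, (ii) robust to how the sample happened to lie under the objective,
and (iii) able to place every cell of every specimen into one common feature
space. `cloudmorph` implements a point-cloud route to this goal: membrane
stacks are segmented into single cells, each cell becomes a cloud of 2000
stochastic landmarks, clouds are registered into common frames of reference,
and a cluster-based embedding condenses each cloud into a short, comparable
feature vector. A synthetic cell generator with known latent parameters
serves as the ground-truth engine for validating the whole chain.

## Segmentation model

The segmentation pipeline is deliberately simple and parameter-stable:
median filter (3x3x3 voxels), Gaussian smoothing (sigma = 3 px), automatic
thresholding, size-limited hole filling, component labeling of the inverted
membrane mask, removal of components below 1000 voxels, watershed expansion
of the surviving components over a re-smoothed topography, and retention of
the largest connected foreground object.

The threshold is chosen by *enclosure counting*: starting at the histogram
mode, offsets 0-10 are scanned and the offset maximizing the number of
connected components of the inverted mask — roughly, the number of cell
bodies fully enclosed by membrane — wins; ties break toward the smallest
offset. Filtering operates in pixel space (anisotropy is deliberately
ignored at this stage; physical units enter when landmarks are scaled to
microns).

Two points in this pipeline are under-determined and were fixed as explicit
design choices:

* **Hole filling is size-limited.** Filling *every* cavity of the membrane
  mask would also fill the enclosed cell bodies that the subsequent labeling
  step is meant to detect, so only cavities smaller than the minimum cell
  size (1000 voxels) are treated as wall defects and filled.
* **Border components are background.** A candidate cell body that touches
  the stack border cannot be a membrane-enclosed cell; such components are
  used as background seeds (configurable via `border_background`). Components
  larger than 10^6 voxels are likewise background, per the default
  `segmentation_config()`.
* **Connectivity.** Component labeling uses 26-connectivity; the enclosure
  count uses 6-connectivity. Both are configurable.

## ISLA and the frames of reference

ISLA converts any non-negative voxel image into a point cloud by drawing
`n_points` landmarks (default 2000) from the multinomial distribution given
by normalized intensities, placing each at its voxel center and scaling to
microns per axis. Cell *shape* uses the 6-connected inner hull of the mask
as input; *content* channels use the masked, background-subtracted
intensities (mean-inside subtraction, clamped at zero).

**TFOR** (tissue frame of reference) aligns whole specimens by a
principal-axis transform of 3000 landmarks sampled from the tissue mask:
axis 1 is the longest (front-rear) axis, axis 3 the shortest (apicobasal)
one. Because an eigenvector's sign is arbitrary, each axis sign is fixed so
that the skewness of the tissue landmarks along that axis is non-negative —
for an anatomically asymmetric tissue this pins the orientation and prevents
180-degree flips; the convention is overridable when a tissue happens to be
skew-symmetric. The frontal-most landmark becomes the origin. TFOR is rigid:
cell sizes and orientations keep their biological meaning.

**CFOR** (cell frame of reference) removes exactly that information. The
cloud is centered and scaled so the magnitudes of all centroid-to-landmark
vectors sum to 1, then re-represented by each landmark's 10th/50th/90th
percentiles of distances to all other landmarks (linear interpolation
between order statistics). The result is provably invariant to translation,
rotation, reflection, and uniform scaling; the package's tests verify
bit-level stability (deviations below 1e-9) under random similarity
transforms.

## Cluster-based embedding (CBE)

Shared reference points make per-cell features comparable across a dataset:
per-cell clouds are centered, condensed from 2000 to 500 landmarks by
k-means, overlaid across a random representative subset of samples (at least
10, at most 25), density-downsampled to at most 200,000 points, and
clustered with k-means (k = 20). For each cell, the feature row concatenates
for every reference center the vector from the center to the centroid of its
25 nearest cloud landmarks — a 3k-dimensional row (60 features at k = 20);
a magnitude variant (k features) is available. Feature matrices are
standardized and PCA-reduced; principal-component signs are anchored so each
kept PC correlates positively with its most defining engineered feature.

The density-dependent downsampling keeps point *i* with probability 1 if its
local density LD_i (neighbors within a radius of 5 times the median pairwise
distance) is below the 3rd percentile of all local densities (TD), and with
probability TD / LD_i otherwise; a uniform subsample enforces the 200,000
cap. Scalability choices: the median pairwise distance is exact up to 20,000
points and estimated from 10^6 random pairs beyond; local densities are
exact up to 50,000 points (grid-hashed counting) and otherwise estimated
against a 20,000-point reference subsample — both estimators are unbiased
and only affect clouds far above the sizes used in validation. When the
neighborhood radius covers the cloud's bounding box every local density
equals n and the step reduces to the uniform cap.

The neighbor count for the feature vector defaults to 25 (exposed as
`n_neighbors`). A moments baseline (`moments_features()`) provides 55
reference descriptors: 3 raw first moments, 6 centralized second moments,
and 46 normalized moments of orders 3-5 over all index triples
(i, j, k) with i + j + k = m, using population standard deviations.

## The synthetic cell generator

Seventeen parameters define a cell: a spine (height along z; lateral end
point offset given as a distance and an angle; one quadratic curvature
coefficient per lateral axis, with the end points pinned — 5 parameters), a
surface given by three logit-normal spine-to-surface distance functions at
azimuths 0/120/240 degrees, each with location, width, and a multiplicative
scale (9), a size multiplier (1), and two rotation angles (2). Point
sampling draws the relative height and the azimuth uniformly and
interpolates the radius linearly (periodically) between the two adjacent
defined azimuths. The logit-normal was chosen because it vanishes at both
ends of the spine, is strictly positive in between, and can be symmetric,
skewed, or bimodal with only two parameters; its normalization constant is
absorbed by the scale parameters. Rotations compose extrinsically, z-axis
first, then y-axis.

By construction exactly one parameter (size) and two parameters (rotation)
leave the CFOR representation untouched; the package's acceptance tests
verify this, and its converse for the other 14 parameters, numerically.

The hyperparameter distributions behind `default_generator_hyper()` are the
package's own calibration (heights near 1 with 10% spread; offsets up to
0.3; logit-normal widths 0.6-1.1 and scales 0.06-0.14; size multipliers
0.6-1.4) chosen once to produce a varied population of plausible,
non-self-intersecting shapes. Rotation angles default to
Uniform(-pi/3, pi/3) rather than a full circle: a full-circle angle is not
an identifiable regression target (rotation by 2 pi is the identity), which
would make the parameter-recovery benchmark ill-posed rather than
informative.

The tissue generator (`generate_membrane_volume()`) is validation plumbing
with no counterpart in real acquisitions: a Voronoi partition of an
ellipsoidal region around evenly spread seeds (k-means centers of random
interior voxels), with ~2-voxel bright walls and optional Gaussian noise.
The partition is computed in voxel space so cells remain well-resolved along
the anisotropic z axis (with the default 0.225 x 0.099 x 0.099 micron
spacing this yields columnar cells, as in real epithelia); the default
canvas scales with the cell count so that cells are ~35-40 voxels across —
comfortably above the pipeline's fixed smoothing scale and minimum component
size. What these fixtures do *not* emulate: deconvolution artifacts,
inhomogeneous illumination, membrane gaps, touching nuclei, or protrusions;
passing segmentation tests on them demonstrates the pipeline's mechanics,
not its performance on degraded real data.

## Parameter recovery as the end-to-end benchmark

`parameter_recovery_benchmark()` generates a population of synthetic cells
(default 2000 here; large-scale studies would use an order of magnitude
more), embeds each cloud with CBE both in CFOR and in the raw
(non-normalized) frame, and asks a k-nearest-neighbor regressor (k = 50; a
mean-of-k predictor carries an intrinsic R^2 bias of -1/k on unrelated
targets, so k is kept large enough for that bias to be negligible) to
predict each generative parameter on a 25% held-out split. The expected
pattern — and what the acceptance suite asserts — is: shape parameters carry
positive signal in CFOR; rotation parameters carry none in CFOR (R^2
within the kNN estimator's small negative bias of -1/k) but substantial
signal in the raw embedding; size behaves like rotation. Individual
parameters differ widely: spine height and logit-normal widths recover
well, whereas azimuthal quantities (offset angle, z-axis rotation) are
weakly identifiable for nearly axisymmetric cells.

## Atlas regression and archetypes

Cross-channel prediction uses multi-output support-vector regression with an
RBF kernel — one independently fitted SVR per target dimension, the
classical reduction of multi-output regression. Inputs and targets are the
first 20 PCs of their embeddings. Training cells are curated by keeping
cells whose secondary-channel intensity lies strictly above the 33rd
percentile and then removing the `floor(0.05 n)` most anomalous cells under
an isolation forest (implemented in the package: 100 trees, subsample 256,
standard path-length score). Hyperparameters come from a logarithmic grid
evaluated on randomly shuffled train/test splits (3 by default); explained
variance is reported as the uniform average over target dimensions of
1 - Var(residual)/Var(target), with the variance-weighted version attached
as an attribute. Spot-count regression uses the 23-feature input of 10 TFOR
PCs + 10 CFOR PCs + 3 TFOR centroid coordinates, and samples with a mean
count per cell below 2 are dropped (boundary inclusive).

Archetype mapping trains an RBF-kernel support-vector classifier with
probability calibration on annotated cells, grid-searching standardization
on/off, PCA with 15/30/50 kept components or none, and penalty/kernel
coefficient decades under stratified 5-fold cross-validation. Class
probabilities (rows sum to 1) feed a PCA "archetype space"; C classes span
at most C - 1 informative dimensions. Group comparisons use the two-tailed
Mann-Whitney U test with caller-declared Bonferroni family sizes (p-values
multiplied and capped at 1; p > 0.01 is reported as not significant) plus
Cohen's d, since at single-cell sample sizes statistical significance alone
is uninformative.

## Tissue-level summaries

Consensus maps pool TFOR centroids of all cells across samples (cells are
pooled rather than averaged per sample first; with roughly balanced samples
the two conventions agree closely). A Gaussian KDE on the pooled centroids,
thresholded at 10% of its range, defines the tissue outline; inside it, the
mapped value at each grid point is the Gaussian-weighted average of per-cell
values with sigma set to the 0.5th percentile of pairwise centroid
distances. The default grid is 256 x 128 over TFOR axes 1-2.

Correlation bigraphs connect engineered features to embedded PCs whenever
|Pearson r| >= 0.3, with signed weights. The engineered nodes are ordered by
minimizing the sum of rank distances between connected nodes weighted by
|r|, via a random local search (transpositions, 3-cycles, and occasional
full reshuffles; only strict improvements are accepted; the search stops
after 2000 consecutive non-improving proposals). For up to 6 engineered
features this matches the exhaustive optimum in the package's tests.

The expanded ("ripped") view scales each cell's centroid in x and y by a
single factor and pastes the voxels unchanged at the new location — cells
separate without deformation; centroid shifts are rounded to whole voxels,
so inter-cell distances scale exactly up to one voxel.

## Engineered features

Per cell: volume (voxel count x voxel volume), surface area, sphericity
(pi^(1/3) (6V)^(2/3) / A, capped at 1 against discretization overshoot),
extents along the TFOR axes (voxel-center ranges plus the projected voxel
footprint, so axis-aligned boxes report exact sizes), TFOR centroid,
orientation angles of the cell's major principal axis against the TFOR
axes, and a surface-smoothness proxy defined here as the ratio of the
cell's surface area to its convex hull's surface area (~1 for smooth convex
cells). Surface areas use the coarea estimate — the integral of the
gradient magnitude of a Gaussian-smoothed indicator (sigma = 1.5 voxels,
physically isotropic) — which is accurate to a few percent on digital balls
of realistic radii; the convex hull is computed by an incremental 3D hull
over the cell's boundary voxels.

## Numerical conventions and degenerate inputs

Arrays are indexed (z, y, x); point matrices carry columns (z, y, x) in
microns; voxel centers sit at (index - 1) x spacing. Percentiles interpolate
linearly between order statistics everywhere (the same rule as the test
oracles). k-means uses k-means++ seeding on unique points, making it robust
to the duplicate landmarks that multinomial sampling produces; fits are
deterministic given a seed. Degenerate inputs fail loudly: empty masks,
all-zero intensity images, single-point clouds, rank-deficient tissue
covariances, and constant contaminant channels all raise errors or warnings
rather than returning silent nonsense.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen for a single-CPU desk machine: segmentation fixtures of
5-30 cells (~1-3 million voxels), clouds of 300-2000 landmarks, a
parameter-recovery population of 2000 cells, and 100-500-replicate
Monte-Carlo checks. These sizes are stated in each test; scaling any of
them up is a matter of the corresponding argument.

## Known limitations

* The segmentation pipeline assumes 8-bit-like intensity statistics and a
  single dominant tissue; it does not attempt protrusion detection,
  deconvolution, or proofreading.
* CBE is not reversible: embedded features cannot reconstruct a cloud.
* The skewness-based orientation convention requires an anatomically
  asymmetric tissue; symmetric tissues need a user-supplied direction.
* The isolation forest and convex hull are compact reference
  implementations; they favor clarity over large-n performance.
* Azimuthal generator parameters are only weakly identifiable for nearly
  axisymmetric synthetic cells; recovery benchmarks average over parameters.
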