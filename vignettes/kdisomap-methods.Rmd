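---
title: "Methods: kernel discriminant isometric mapping with LBP features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel discriminant isometric mapping with LBP features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdisomap)
```

## The problem

Facial expression images of the same person vary smoothly — a smile unfolds
along a continuous trajectory in image space — so each expression class is
better described as a low-dimensional nonlinear manifold than as a Gaussian
blob. Linear projections (PCA, LDA) flatten that structure; unsupervised
manifold learners (Isomap) preserve it but ignore class labels, so classes
that interleave along the manifold stay interleaved in the embedding. This
package implements a supervised manifold embedding, kernel discriminant
isometric mapping (KDIsomap), that preserves within-class manifold geometry
while expanding the gaps between classes, together with the texture features,
baselines and evaluation protocol needed to use and test it end to end.

## Feature extraction: spatially enhanced uniform LBP

A local binary pattern labels each pixel by thresholding a circular
neighbourhood of `P` points at radius `R` against the centre intensity
(neighbour >= centre contributes bit 1; bit p is the p-th point starting
"up" and moving counter-clockwise, least significant first — any fixed
convention works, this one is frozen and shared by `basic_lbp()` and
`circular_lbp()`). Patterns with at most two circular 0/1 transitions
("uniform" patterns) each get their own histogram bin; the rest share one
bin, giving 59 bins at P = 8. The image is partitioned into a grid of
regions, one histogram per region, and the histograms are concatenated, so
the descriptor encodes texture and its spatial layout at once. With the
default `LBP^{u2}_{8,2}` operator and a 6 x 7 grid on a 110 x 150 face crop
the descriptor has 59 x 42 = 2478 entries.

Two geometric conventions matter:

* **Borders.** Labels are computed only where the full circular
  neighbourhood fits, so a border of `ceiling(R)` pixels is excluded and
  the grid partitions the *labeled* area (146 x 106 at R = 2), not the raw
  image. This avoids inventing padding values.
* **Grid.** 110 and 150 are not multiples of 18 and 21, so "18 x 21 pixel
  regions" cannot tile the crop exactly. The package keeps the 6 x 7 = 42
  region count and the 2478-length descriptor as the hard constraints and
  tiles with near-equal regions (widths 18 or 19, heights 21 or 22, the
  larger ones trailing).

Face crops are produced by `normalize_face()`: a similarity transform
(rotation plus uniform scale) brings the eye centres to a 55-pixel
separation, then a 110 x 150 window is cropped with the eyes placed
symmetrically about the vertical midline at one third of the output height —
consistent with the convention that a face is roughly two eye-distances wide
and three tall. Resampling is bilinear; out-of-range samples replicate edge
pixels and warn.

**Histogram scaling.** `lbp_features()` returns raw counts by default
(`normalize = TRUE` divides each region block by its pixel count). The
kernel pipeline below, however, fixes the Gaussian bandwidth at
`sigma = 1`, which presumes feature distances of order one. Raw-count
descriptors of 110 x 150 images have squared distances of order 10^4-10^6,
which drives every kernel value to zero and every kernel distance to its
saturation value sqrt(2) — the discriminant matrix then carries no
information at all. All evaluation code in this package therefore extracts
*normalized* histograms (squared distances of order 0.1-10), and we
recommend the same to users; the raw-count default is kept only for the
descriptor itself, where counts are the natural unit.

## The embedding family

All six fitted models share one interface: a fit function returning a
classed object with `predict()` (out-of-sample projection), `print()`,
`summary()`, `plot()` and `fitted()`.

### Kernel Isomap

`kisomap()` is Isomap with a kernel-style out-of-sample rule:

1. k-NN graph on Euclidean distances (k = 10 by default; the graph is
   union-symmetrized, ties break to the smaller index);
2. all-pairs shortest paths (Dijkstra) approximate geodesic distances;
3. double centering `K(D^2) = -1/2 H D^2 H` turns squared geodesics into a
   Gram matrix;
4. top-d eigenvectors give coordinates `Y = Lambda^{1/2} V^T`.

Graph geodesics are not exactly Euclidean, so `K(D^2)` generally has some
negative eigenvalues. Two remedies are implemented:

* **Clamping (default, `shift = "none"`).** Only the top-d eigenvalues are
  used; a negative retained eigenvalue is clamped to zero with a warning.
  The low-dimensional geometry is untouched.
* **Constant shifting (`shift = "mercer"`).** Adding a constant c to every
  off-diagonal geodesic distance makes the kernel
  `K* = K(D^2) + 2c K(D) + 1/2 c^2 H` positive semi-definite for every c at
  or above a critical value c*, the largest eigenvalue of the block matrix
  `[[0, 2K(D^2)], [-I, -4K(D)]]` (`shift_constant()`); the package then
  uses `c = max(c*, 0)`. Here `K(D)` is the double-centered *first-power*
  geodesic matrix — implied by the constant-shift construction though
  rarely written out.

The shift buys a genuine Mercer kernel (every eigendirection nonnegative)
but at a measurable geometric price: c is added to *every* pairwise
distance, and on curved data c* is of the same order as the distances
themselves, which visibly distorts low-dimensional isometry. Since the
clamped embedding already yields a positive semi-definite rank-d Gram
matrix and an identical out-of-sample rule, the package defaults to
clamping and treats the shift as the opt-in construction it is; the
shift machinery is exported and property-tested regardless (the PSD
guarantee holds to 1e-8 on random datasets).

Numerical notes: eigenvalues of the non-symmetric block matrix may acquire
small imaginary parts; the largest real part is used if its imaginary part
is below `1e-6 * max(1, |real|)`, otherwise the code falls back to bisection
on the PSD condition. The bisection deflates the all-ones direction, which
is an exact null vector of `K*(c)` for every c and would otherwise flip the
sign test on rounding noise. Eigenvector signs are fixed by making each
vector's largest-magnitude entry positive.

### Kernel discriminant Isomap

`kdisomap()` replaces step 1's metric. Features are first mapped into a
reproducing kernel Hilbert space by the Gaussian kernel
`kappa(x, y) = exp(-||x - y||^2 / 2 sigma^2)` (sigma = 1); the kernel
Euclidean distance is
`d_k^2 = kappa(x,x) - 2 kappa(x,y) + kappa(y,y) = 2 - 2 kappa`. The
discriminant distance then depends on the labels:

* same class: `D = 1 - exp(-d_k^2 / beta)` — bounded in [0, 1), compressing
  within-class spread;
* different class: `D = exp(d_k^2 / beta) - alpha` — at least `1 - alpha`,
  expanding between-class gaps.

Both branches increase monotonically in `d_k`, so neighbourhood order — the
only thing the k-NN graph consumes — is preserved within each branch. At
`alpha = 0` every interclass dissimilarity strictly exceeds every
intraclass one; `alpha` in (0, 1] softens that guarantee, letting tight
cross-class neighbours stay close. The two branches are deliberately
discontinuous across the class boundary: that gap is the discriminant
mechanism, and no smoothing is applied.

`beta` is a density scale: by default (`beta = "auto"`) it is the mean
kernel Euclidean distance over all unordered sample pairs, self-pairs
excluded (including the N zero diagonals would only dilute the average).
The exponent uses `d^2 / beta` with beta averaged on the first power — the
units are consistent by convention only; the choice is frozen and
documented. An all-identical dataset gives beta = 0 and a clear error,
since the formula divides by beta.

A practical consequence of the discriminant metric: at small k the k-NN
graph often splits into one component per class (interclass edges cost at
least 1 - alpha). `geodesic_distances()` refuses disconnected graphs with
an error naming the component sizes and suggesting a larger k;
`auto_connect = TRUE` instead bridges components with their shortest
inter-component dissimilarity edge, repeatedly, and is the default inside
the cross-validation harness where refusing a fold would abort a sweep.

### Out-of-sample projection

New points are projected by the kernel trick: a centered kernel column
`k~(x)` against the training set is built and projected,
`y = Lambda^{-1/2} V^T k~(x)`. For the isomap family the column comes from
graph geodesics: the new point is linked to its k nearest training points,
its geodesic to every training point i is
`min_j [edge(x, j) + d_geo(j, i)]` over those links, the (optionally
c-shifted) squared column is centered with the training row/column means,
and training points passed back through reproduce their training
coordinates exactly (a point within 1e-8 of a training point snaps to its
geodesic profile, which keeps the projection continuous at duplicates even
under the shift).

A test point's label is unknown, so the discriminant distance cannot be
evaluated for KDIsomap test edges. The package uses the bounded intraclass
transform `1 - exp(-d_k^2 / beta)` of the kernel distance for
test-to-training edges: it is monotone in the kernel distance, so
neighbour ranking is preserved, and bounded like the intraclass branch.
This is a documented extension choice (recorded in the model's `oos_rule`
field), not something the discriminant construction dictates.

### Baselines

`pca_embed()` (maximal retained variance, via `prcomp`), `lda_embed()`
(Fisher ratio; solved in the span of the centered data with a ridge of
1e-6 x trace on the within-class scatter, the standard remedy for D >> N),
`kpca_embed()` (eigendecomposition of the double-centered kernel matrix)
and `klda_embed()` (kernelized Fisher problem in the dual, same ridge
convention) complete the comparison set. LDA and KLDA expose at most
c - 1 dimensions for c classes. All share the eigen-sign convention and
the `predict()` out-of-sample interface (linear maps for PCA/LDA, centered
kernel columns for KPCA/KLDA).

## Evaluation protocol

`run_experiment()` reproduces the recognition protocol: subject-grouped
10-fold cross-validation (folds partition *subjects*, so no person appears
on both sides of a split; fold sizes differ by at most one subject, and the
assignment is the experiment's only source of randomness), per-fold fitting
on the training folds only, out-of-sample projection of the held-out fold,
1-NN classification with the Euclidean metric (ties to the smallest
training index), and accuracy recorded per (method, dimension, alpha) cell
as mean +/- sd across folds. The reported uncertainty is the plain standard
deviation over the 10 fold accuracies. Spectral methods are fitted once per
fold at the largest requested dimension and sliced, since their coordinates
are nested.

The dimension grid merges a coarse sweep (2 to 100 in steps of 5) with a
fine sweep (2 to 10 in steps of 1); LDA/KLDA are capped at c - 1. The
KDIsomap constant is swept over alpha = 0, 0.1, ..., 1. Two selection
protocols are provided because published sweeps are often ambiguous about
where alpha was tuned:

* `alpha_mode = "inner"` (default): alpha is chosen per dimension by an
  inner 5-fold subject-grouped cross-validation inside the training folds —
  no information from the held-out fold reaches the choice;
* `alpha_mode = "outer"`: every (dimension, alpha) cell is reported and the
  best cell is read off the outer test accuracy. This is optimistic and
  labeled as such; it exists for comparability with sweep-style reporting.

Leakage is checked by construction and by test: corrupting the samples of a
held-out fold must leave that fold's fitted quantities (beta, c*)
bit-identical.

## Synthetic data

Two generators make every claim testable without external data.

`make_swiss_roll(n, noise_sd, seed)` samples the classic roll
`(t cos t, h, t sin t)`, t uniform on [1.5 pi, 4.5 pi], h uniform on
[0, 21], and returns the true unrolled coordinates (spiral arc length,
height), an exact isometry at zero noise, so isometry recovery can be
scored as the Pearson correlation between embedded and true pairwise
distances. Two honest caveats, both measured in development and covered in
tests at the sizes stated there: (i) k-NN graph shortest paths between
non-adjacent samples overestimate straight-line distance by a few percent
(the intrinsic stretch of graph paths) — correlations remain above 0.999 on
the roll at n = 800, k = 10, but pointwise 1% agreement between embedded
and true distances is not a property graph geodesics can deliver at fixed
k; (ii) for some samples the sparse outer boundary of the roll produces a
single "short-circuit" edge one whorl inward — the classic Isomap
topological failure — which degrades the geodesics themselves regardless of
implementation (the shortest-path stage is verified against an independent
Floyd-Warshall oracle).

`make_expression_dataset()` emulates a labeled face-expression database:
each of 7 classes is a distinct procedural texture manifold (an oriented
sinusoidal grating with class-specific orientation and frequency, plus two
Gaussian blobs whose centres move smoothly with a per-image latent
parameter, so each class traces a one-parameter nonlinear image manifold);
each of 10 subjects contributes a fixed smooth low-frequency intensity
field (amplitude 12 gray levels); pixel noise is Gaussian (sd 4 gray
levels), and intensities are clipped to [0, 255]. Images default to
110 x 150 so the exact 6 x 7 grid and 2478-length feature path are
exercised. Subjects are balanced across classes so subject-grouped folds
are class-balanced in expectation. The `separation` knob interpolates
between a class-specific and a shared texture: at 0 all classes are
identically distributed (recognition falls to chance, 1/7), and the knob is
monotone. The defaults are deliberately separable — the set is a fixture
whose contract is that the full LBP + KDIsomap + subject-CV pipeline
recovers at least 85% accuracy, not a claim about real faces. What passing
tests on this set demonstrates is that the pipeline is wired correctly
(features discriminate, folds do not leak, embeddings preserve class
structure); what they do not show is robustness to pose, illumination
direction, occlusion, registration error or the inter-subject appearance
variation of real databases, none of which the generator emulates.

## Problem sizes used in the checks

The shipped tests and the acceptance script run, among others: the swiss
roll at n = 800 (k = 10, d = 2); the Mercer-shift PSD property on 20 random
datasets of 20-60 points; and the supervised-vs-unsupervised comparison on
10 generator seeds of the default 140-image expression set with the reduced
sweep d in {2, 10, 20}, alpha in {0, 0.5, 1} under outer-mode selection.
These sizes were chosen so the full suite exercises every code path at
meaningful scale while remaining comfortable to run routinely.

## Known limitations

* Isomap-family methods require a connected neighbourhood graph; the
  discriminant metric makes disconnection at small k routine, and
  auto-bridging (the fallback) adds edges the metric did not ask for.
* The out-of-sample rule for KDIsomap treats test points as unlabeled
  intraclass neighbours of everything; when classes overlap heavily this
  underestimates test-to-training dissimilarity across classes.
* `sigma`, k and the histogram scaling interact: the Gaussian kernel is
  informative only when typical squared feature distances are of order
  `sigma^2`. The package fixes sigma = 1 and normalizes histograms in its
  pipelines rather than tuning sigma per dataset.
* Complexity is O(n^3) time / O(n^2) memory in the number of training
  samples for all kernel methods (eigendecompositions of n x n matrices;
  the block matrix of the Mercer shift is 2n x 2n). No landmark or sparse
  approximations are implemented.
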