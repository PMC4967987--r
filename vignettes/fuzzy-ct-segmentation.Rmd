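---
title: "Fuzzy clustering for nodule ROI detection in thoracic CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy clustering for nodule ROI detection in thoracic CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyCT)
```

## The problem

Computer-aided detection of pulmonary nodules is usually organised as a
multistage pipeline: lung isolation, candidate region-of-interest (ROI)
detection, then classification of candidates.  This package implements the
ROI detection stage as unsupervised fuzzy clustering of voxel attenuation
values (Hounsfield Units).  The goal of the stage is not a final diagnosis
but a drastic reduction of the search space: mark as many true nodule voxels
as possible (high TP%) while marking few non-nodule voxels (low FP%), so
that a downstream classifier has a tractable and trustworthy candidate set.

Within a lung mask, a thoracic CT slice has three broad intensity
populations: air-filled parenchyma (around -850 HU), vessels and other soft
structures (around 0--60 HU), and nodules, whose attenuation is midrange.
Intensity alone does not separate nodules from vessels, which is why the
model family below adds kernelized distances and spatial neighborhood
information to the basic clustering machinery.

## The model family

All five algorithms partition the $n$ eligible voxels with intensities
$x_k$ into $c$ fuzzy clusters with centroids $v_i$, via membership values
$u_{ik} \in [0,1]$, $\sum_i u_{ik} = 1$.  A fuzzifier $m > 1$ controls
partition softness.  Iteration alternates a membership update and a
centroid update until the maximum absolute centroid change falls below a
threshold $\epsilon$.

**FCM** minimises $J_m = \sum_k \sum_i u_{ik}^m (x_k - v_i)^2$ with the
classical updates

$$u_{ik} = \Big[\textstyle\sum_j \big(|x_k - v_i| / |x_k - v_j|\big)^{2/(m-1)}\Big]^{-1},
\qquad
v_i = \frac{\sum_k u_{ik}^m x_k}{\sum_k u_{ik}^m}.$$

**KFCM** replaces the squared distance with a kernel distance
$1 - K(x_k, v_i)$, emulating clustering after a nonlinear map into a
higher-dimensional feature space:

$$u_{ik} = \frac{(1 - K(x_k, v_i))^{-1/(m-1)}}{\sum_j (1 - K(x_k, v_j))^{-1/(m-1)}},
\qquad
v_i = \frac{\sum_k u_{ik}^m K(x_k, v_i)\, x_k}{\sum_k u_{ik}^m K(x_k, v_i)},$$

with $K$ evaluated against the previous iteration's centroids.  Both a
Gaussian radial basis kernel and a polynomial kernel $(xy + b)^d$ are
available; all CT work here uses the Gaussian.

**SFCM** adds a spatial function
$h_{ij} = \sum_{k \in NB(x_j)} u_{ik}$ -- the sum of the window neighbors'
memberships to cluster $i$ -- and reweights memberships multiplicatively:

$$u'_{ij} = \frac{u_{ij}^p\, h_{ij}^q}{\sum_k u_{kj}^p\, h_{kj}^q},$$

after which centroids are recomputed from $u'$ with the FCM formula.  Each
outer iteration performs a single FCM membership evaluation against the
current centroids (not a nested FCM run), then the spatial steps.

**SKFCM** keeps the kernelized memberships but penalises disagreement with
the neighborhood through a penalty of weight $\alpha$: the kernel distance
in both updates is augmented by $(\alpha/N_R) \sum_{r \in N_k}(1 - K(x_r,
v_i))$, where $N_k$ is the window around voxel $k$ *excluding* the voxel
itself and $N_R$ its cardinality.

**MSKFCM** composes the two ideas: kernelized memberships, the
$u^p h^q$ spatial reweighting (window including the centre), and
kernel-weighted centroids computed from the spatially weighted memberships.
It is the algorithm of choice for automated ROI detection here: with three
clusters, the nodule consistently lands in the midrange cluster, so no
operator interaction is needed to select it.

### Reductions

The family is internally consistent, and the test suite asserts these
identities numerically: SFCM with $p = 1, q = 0$ retraces FCM; MSKFCM with
$p = 1, q = 0$ retraces KFCM; SKFCM with $\alpha = 0$ reproduces KFCM
(for this reason the package accepts $\alpha \in [0, 1)$ rather than the
open interval); and KFCM with a very large Gaussian $\sigma$ tracks FCM,
because $1 - K \approx (x - v)^2 / (2\sigma^2)$ is then proportional to the
squared distance.

## Parameters

* `clusters` ($c$): 3 by default.  Three clusters (air, nodule-like,
  vessel/tissue) give the most stable nodule assignment; with $c = 3$ the
  nodule cluster is auto-selected as the midrange centroid.
* `fuzzifier` ($m$): 2, the conventional choice; larger values soften the
  partition.
* `kernel` ($\sigma$, HU): Gaussian width.  Sensible CT values lie in
  150--750 HU; 300 is the default.  Two denominator conventions circulate
  in the literature, $\exp(-d^2/2\sigma^2)$ and $\exp(-d^2/\sigma^2)$; the
  package exposes both via `variance_scale` (they coincide under
  $\sigma' = \sigma\sqrt2$) and defaults to the former for KFCM/MSKFCM and
  the latter for SKFCM, following the conventions of each algorithm's
  source formulation.
* `p`, `q`: spatial weighting exponents, non-negative, best results in
  $[0, 2]$; defaults $p = q = 1$.
* `alpha`: SKFCM penalty weight, $[0, 1)$, default 0.1.
* `neighborhood`: a 2D $s \times s$ in-slice window or a 3D rectangular
  prism $s \times s \times d$ spanning adjacent slices (default $3 \times
  3$, or $3^3$ in 3D).  Windows truncate at volume boundaries; spatial sums
  and $N_R$ count only in-bounds, in-lung-mask neighbors, so no padding
  values ever enter a sum.  A voxel with no eligible neighbors simply drops
  its spatial term.
* `epsilon`: stopping threshold on the max-norm centroid change, 1e-3 HU by
  default; `max_iter` caps iteration at 200.  Hitting the cap reports
  `converged = FALSE` rather than failing.

### Initialization

Either operator samples (at least one intensity or voxel coordinate per
cluster; the initial centroid is the sample mean) or reproducible random
draws from the eligible intensity range, controlled by a seed.  Initial and
updated centroids are kept pairwise distinct by perturbing duplicates with
the smallest representable step -- duplicate centroids would make the
membership ratio undefined.

### 2D versus 3D processing

With a 2D window on a multi-slice volume, each slice is fit independently
(its own centroids and iteration count), matching the slice-by-slice
protocol of thoracic CT reading; a 3D window fits the volume jointly, the
prism spanning the previous and following slices.  When all slices of a
volume are identical, 3D MSKFCM with a $3^3$ window reproduces the 2D
labels exactly -- the per-voxel scaling of $h$ cancels in the membership
normalisation -- which the suite uses as a consistency check.

## Numerical conventions

* **Singularities.**  A voxel coinciding with one or more centroids (zero
  distance, or $1 - K = 0$) receives crisp membership split equally among
  the coinciding clusters, preserving the sum-to-one invariant.
* **Zero spatial normaliser.**  If all $u^p h^q$ weights vanish at a voxel
  (possible when $p = 0$ and the voxel has no eligible neighbors), its
  unweighted memberships are kept and a warning is emitted.
* **Defuzzification** is the per-voxel argmax, ties broken toward the
  lowest cluster index.
* **Objective traces.**  The FCM objective is recorded per iteration and is
  non-increasing (asserted in tests); KFCM and SKFCM record their kernel
  objectives.  SFCM and MSKFCM have no associated single objective -- the
  corresponding base objective evaluated at the spatial memberships is
  recorded for diagnostics but carries no monotonicity guarantee.
* **Fixed-point consistency.**  After convergence the reported memberships
  are recomputed from the final centroids (for spatial algorithms, the full
  membership--spatial chain), so the stored state is exactly the fixed
  point implied by the stored centroids.

## The synthetic phantom

`generate_phantom()` renders an elliptical "lung" of -850 HU parenchyma in
a 40 HU chest wall, with 30 HU vessel tubes and midrange (-50 HU) spherical
nodules, adds seeded Gaussian noise, and clips to the 12-bit HU range
$[-1024, 3071]$.  The default conditions are a $64 \times 64 \times 3$
volume, one radius-4 nodule, two vessels, and noise sd 20 HU -- the HU
separations mirror the qualitative ordering of real thoracic CT (air
$\ll$ nodule $<$ soft tissue), and the nodule/parenchyma separation is 40
noise standard deviations, so centroid recovery is a meaningful check, not
a coin flip.  Volume and window sizes were chosen so the entire suite runs
in well under a minute per algorithm.

What the phantom does **not** emulate: textured parenchyma, partial-volume
boundaries, juxtapleural nodules merged with the chest wall (these are lost
at the lung-isolation stage, which this package does not implement),
scanner reconstruction artifacts, or anisotropic voxel spacing.  Passing
tests on the phantom therefore demonstrate correctness of the algorithms
and their stated properties, not clinical performance on LIDC-style data.

`generate_consensus()` emulates radiologist-consensus masks (scores
0--1000) by scoring erosion depth: nodule cores score 1000 and each ring
nearer the boundary scores 200 less (floored at 100).  This reproduces the
*structure* of consensus data -- agreement in cores, divergence at rims --
and makes `consensus_filter(mask, 800)` exercisable; it claims no fidelity
to any actual consensus scoring formula.  `add_salt_pepper()` injects
impulse noise at the 12-bit extremes into the eligible voxels.

## Evaluation methodology

`tp_fp_rates()` scores a predicted ROI mask voxelwise: TP are nodule voxels
labeled nodule, FN nodule voxels missed, FP non-nodule voxels labeled
nodule; `tp_pct = 100·TP/|truth|`.  The FP percentage needs a denominator
choice, and the package defaults to `100·FP/|predicted|` (the complement of
precision), which matches the scale of published per-slice FP figures for
tiny nodules inside large lungs; the alternative `|domain \ truth|`
denominator is available via `fp_denominator = "domain"` and is recorded in
every record.  Slices with empty truth report `tp_pct = NA` rather than
being dropped.  Evaluation restricts to the lung mask when one is present.

`parameter_sweep()` implements the tradeoff-sampling methodology: run the
algorithm across a parameter grid, select the nodule cluster of each fit,
score per slice, and collect one record per (combination, slice).  Sampling
broadly enough traces the attainable TP-vs-FP operating points of an
algorithm the way an ROC curve would for a thresholded detector -- the
right tool when the stage's purpose is search-space reduction rather than
final classification, and when only nodule (not full-scene) ground truth
exists.  A failed combination becomes a record with the error message, so a
sweep never aborts, and `tradeoff_table()` orders records by FP then
descending TP for reading off operating points.

### A degeneracy worth knowing about

Multiplicative spatial reweighting cannot repair *crisp* memberships: if
$u_{ik} \in \{0, 1\}$, then $u^p h^q$ leaves the argmax unchanged whenever
the labeled cluster has any support in the window.  With three clusters and
impulse noise at exactly 3071 HU, FCM parks a centroid on the salt atoms,
their memberships become crisp, and SFCM then reproduces FCM's labels
exactly -- the denoising comparison is degenerate.  On a two-region phantom
(c = 2), where corrupted voxels stay soft, the spatial variants repair them
as intended (the suite asserts strictly fewer mislabels for SFCM vs FCM and
MSKFCM vs KFCM there).  Kernelized centroids are robust to the outliers
themselves, which is why MSKFCM also improves on KFCM in the three-cluster
setting.

## Problem sizes and runtime

Oracle-equivalence tests compare every update rule against naive scalar
loops on $8 \times 8$ images; solver properties use 12--32 voxel slices
and the standard $64 \times 64 \times 3$ phantom; the command-line pipeline
test runs all five algorithms in 2D and 3D plus a five-point $\sigma$
sweep, twice, verifying byte-identical outputs.  The full suite completes
in well under a minute on one CPU.

## Known limitations

* Clustering uses scalar intensity only -- no multifeature vectors, by
  design, since attenuation is the paper-of-record's sole feature.
* Lung isolation is out of scope; a lung mask must be supplied (or comes
  free with the phantom).
* Supported volume formats are NIfTI (lossless), 16-bit TIFF stacks
  (lossless for integer HU), and PNG stacks (8-bit, display only); DICOM
  series and NRRD are not read.
* LIDC-dialect XML parsing covers reading sessions, per-slice `edgeMap`
  contours (filled, boundary pixels inclusive), and vote-count consensus
  scaling (votes/readers × 1000); the exact historical consensus formula
  is not public, so the scaling is an explicit emulation.
* Window shapes are rectangles/prisms only; spherical or rhomboid
  neighborhoods are not implemented.
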