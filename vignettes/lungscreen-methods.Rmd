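---
title: "Methods: phantom-based lung-carcinoma screening"
author: "lungscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based lung-carcinoma screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lungscreen)
```

This vignette documents the models, the tunable parameters and the design
decisions behind the package — the things a maintainer would want to know
before changing a default. It states no empirical numbers of its own; the
test suite and `scripts/acceptance.R` compute every figure the package
claims.

## Overview

The package screens 2-D grayscale chest images for lung carcinoma in six
stages:

1. **Denoising** by an intra-class-variance anisotropic diffusion filter
   (I-ADF).
2. **Lung-field extraction**: contrast stretching, multi-level Otsu
   thresholding, and per-lung convex hulls.
3. **Segmentation**: region growing from four "knuckle" seed points, one
   per lung-field quadrant, chosen by a Bates-distributed coati
   optimization (COA) metaheuristic.
4. **Feature extraction**: gradient-histogram, spectral-flatness, profile,
   on-rib and on-vessel blocks per quadrant (21 features x 4 quadrants).
5. **Feature selection**: 2x2 chi-square scoring with a binomially derived
   significance level.
6. **Classification and risk screening**: a small residual network with a
   learnable parametric ReLU (PResNet) labels images Normal/Abnormal;
   abnormal images are split into high/low risk from on-rib evidence and
   the nodule-candidate intensity.

Everything runs on a built-in synthetic chest phantom with full ground
truth, so each stage is testable without external data.

## The diffusion model

The denoiser integrates `dI/dt = div(D grad I)` with a diffusion tensor
whose eigenvalues come from three gains: the full 5x5-window gain `C`, a
planar gain `Cplanar` from a stencil spanned by the structure-tensor
eigenvectors `(e2, e3)`, and a linear gain `Clinear` from a 7-sample
stencil. The eigenvalue ladder is

```
alpha1 = 1 - C
alpha2 = alpha1 + (3/2)(1 - Cplanar)
alpha3 = alpha2 + 3 (1 - Clinear)
```

with `alpha1` acting along the dominant gradient direction `e1`. The gain
is `C = exp(-v / (k^2 m^2 + eps))` with `v` the *unnormalized* sum of
squared deviations over the stencil and `m` the stencil mean: 1 in a
perfectly homogeneous neighborhood, decaying as intra-class variance
grows. Under this convention diffusion is *weaker* where the neighborhood
is already uniform and saturates where variance is large, so the filter
trades edge sharpness for noise removal; the total diffusion time
(`iterations x dt`) is what decides whether the trade is favorable.

Numerical choices:

* **Scheme.** Conservative face fluxes with zero-flux (Neumann)
  boundaries: the global intensity sum is preserved to machine precision
  before clipping, and the forward-difference normal flux damps
  checkerboard noise that a central-difference scheme would leave
  untouched.
* **Stability.** Explicit Euler is stable for
  `dt <= 1/(2 d maxAlpha)`; the in-plane ladder can reach
  `1 + 3/2 + 3 = 5.5`, giving a worst-case bound of about `0.045` for
  `d = 2`. The first iteration checks the attained bound and refuses a
  larger `dt` by name. The default `dt = 0.01` with 10 iterations keeps
  the total diffusion time small enough that noise removal in homogeneous
  regions outpaces edge erosion on 128x128 phantoms with Gaussian noise of
  sigma 0.05.
* **Gain sensitivity.** `k = 1` in the denoiser: with the unnormalized
  25-sample variance and phantom intensities around 0.25, that places the
  homogeneous-region gain near `exp(-1)`, so the gains genuinely span
  (0,1) instead of saturating at 0. (`gainCoefficient()` itself defaults
  to `k = 0.1` for stencil-free use with normalized variances.)
* **2-D images.** The structure tensor is computed in-plane; `e3` is the
  out-of-plane axis, so the planar stencil collapses onto `e2` and the
  linear stencil runs along `e2` as a surrogate. Stacks (`D >= 3`) are
  denoised slice by slice with the same in-plane tensor; a fully 3-D
  tensor path is out of scope for this release.

## Lung-field extraction

Otsu's criterion is applied in its two-threshold (3-class) form: the image
is background / lung field / thorax, and the upper split separates the
lung class from the brighter thorax. When large bright lesions claim the
top intensity class, a three-threshold (4-class) split is tried,
middle threshold first; each candidate threshold is accepted only if it
yields one or two interior dark components of at least 0.5% of the image.
Before labeling, a small opening removes isolated dark noise pixels and a
7-px closing bridges the thin bright structures (rib bands, vessels) that
would otherwise cut a lung field into strips. The final mask is the union
of the per-component convex hulls — the smallest convex polygons around
each lung field — and the region is the image with everything outside the
mask zeroed.

## Seed selection and region growing

Seeds are found by one COA run per lung-field quadrant. Each candidate
position is scored by the within-region variance of the region grown from
it (threshold `c * sd(5x5 at seed) + floor`, defaults `c = 3`,
`floor = 0.05`); a candidate whose region anchors less than 20% of the
quadrant's lung-field pixels is penalized, because a "knuckle" point is
meant to anchor a substantial homogeneous part of the lung, not a
micro-region on a rib or nodule whose variance is trivially zero. The
optimizer uses the Bates distribution (mean of `phi` uniforms,
`phi = 3`) for its random steps, a greedy acceptance rule in both the
iguana-hunt and predator-escape phases, and local bounds that shrink as
`1/tn`. `coatiOptimize()` defaults to `m = 20`, `Tn = 50`; the per-image
seed search uses `m = 10`, `Tn = 15` — four quadrant searches run per
image and the fitness landscape (variance of a grown region) is cheap but
flat, so the larger budget buys nothing measurable.

The four grown regions are closed with a 5-px disc (recovering the thin
vessels and rib bands that the threshold excludes but the lung-field truth
contains), intersected with the lung mask and each with its own quadrant —
the "four parts" of the segmentation. On homogeneous parenchyma all four
regions would otherwise grow into the same connected lung field, and the
gray-value overlap rule alone would split them by noise; the quadrant crop
makes the decomposition well defined, and the gray-value rule
(`resolveOverlaps()`) still handles any residual contested pixels.

## Features

Each quadrant sub-image is the enhanced image cropped to the quadrant's
lung-field bounding box (padded to at least 8x8). Per sub-image:

* **Gradient block** (7): 64-bin histogram of Sobel magnitudes over the
  grown-region pixels on a fixed [0,1] range; the two tallest local
  maxima give the mode spacing, the +/-2-bin mode areas, and the height
  ratio normalized by spacing; skewness `g1`, excess-free kurtosis `b2`
  and the bimodality coefficient `(g1^2+1)/b2` summarize the sample.
* **Spectral flatness** (1): geometric over arithmetic mean of the non-DC
  Fourier magnitudes of the zero-mean masked crop.
* **Profile block** (4): 16 vertical columns through the mask of the
  Sobel-magnitude image (ribs are near-horizontal, so vertical profiles
  cross them); per profile a rib-cross indicator (smoothed peak above
  mean + 2 sd), the max/min positive peak ratio, the min/max first
  difference, and the mean absolute second difference, averaged.
* **On-rib block** (6): Canny edges grouped into chains (with a one-pixel
  closing so the two contours of a thin band merge); chains at least 15 px
  long with |principal-axis slope| <= 0.5 are rib candidates. The block
  reports the distance from the nodule-candidate centroid to the nearest
  rib chain, the median spacing of consecutive rib-chain centroids, the
  flag `d_min < inter_rib`, and the nearest chain's length, slope and
  eccentricity.
* **On-vessel block** (2): product of the two longest non-rib chain
  lengths over the sub-image area, and the inverse distance from the
  nearest chain to the sub-image center (floored at 0.5 px).
* **Nodule-candidate peak** (1): the feature blocks above list 20
  quantities; the risk screen additionally needs a lesion intensity, so
  the 21st feature is the peak intensity of the brightest connected blob
  above the 99th percentile of the quadrant's lung field. It is read off
  the *denoised* image (passed as `reference`), not the enhanced one: the
  robust contrast stretch saturates its top percentile, which would erase
  exactly the rib(0.75)-versus-nodule(0.9) contrast that the risk
  threshold `tauRisk = 0.8` discriminates.

Every degenerate case (no chains, constant sub-image, empty mask) maps to
a finite value — zeros for magnitudes and flags, the sub-image diagonal
for unbounded distances — so the 84-vector never carries NaN or Inf.

## Selection, classifier, risk screen

Features are median-binarized against the class labels and scored with the
2x2 chi-square statistic `e (WZ - YX)^2 / ((W+Y)(X+Z)(W+X)(Y+Z))`, which
is algebraically the Pearson statistic. The significance level is the
binomial pmf value `R = choose(e, rho) g^rho (1-g)^(e-rho)` with defaults
`e = 20, rho = 1, g = 0.05`; the critical value is the chi-square quantile
at `1 - R` with one degree of freedom (via `stats::qchisq`, the
regularized incomplete-gamma inversion). A plain `alpha` can override `R`.
If nothing passes, the top 10 by score are kept with a warning.

PResNet consumes the selected features as a 1-channel sequence:
convolution stem, `nBlocks = 3` residual blocks (`conv -> p-ReLU -> conv`
plus identity skip), max pooling with stride `kappa = 2`, and a 2-logit
fully connected head; an image mode with 2-D convolutions exists for
completeness, but the feature-vector mode is canonical. The p-ReLU slope
(init 0.25) is a single learnable parameter. Inputs are z-scored by the
training statistics (stored in the model); training is Adam
(lr 1e-3, weight decay 1e-4 on weights only) on softmax cross-entropy for
50 epochs, fully seeded, with forward/backward passes written directly in
array algebra so runs are bit-reproducible across platforms.

The pipeline arranges the classifier input family-major: every family
with at least one selected quadrant column contributes all four of its
quadrant values, adjacent and in quadrant order, and the pipeline's
PResNet instance uses one residual block with pooling stride 4. The
stride-4 max pooling then computes per-family maxima across the four
quadrants after the convolutional stem — a direct encoding of the
screening semantics that an image is abnormal when *any* quadrant shows
lesion evidence (a lesion lives in one quadrant, so per-quadrant averages
dilute it). `presnetConfig()` itself keeps the general defaults
(3 blocks, stride 2) for standalone use on unstructured vectors.

Risk: a Normal prediction is risk `none`; an Abnormal prediction is
`high` when any quadrant's on-rib flag is set or the maximum
nodule-candidate peak exceeds `tauRisk = 0.8` (between the rib and nodule
palette intensities), else `low`.

## The phantom generator

The generator emulates an axial-CT-like chest slice at 128x128: a thorax
ellipse (intensity 0.45) on dark background (0.05), two lung-field
ellipses (0.25), three rib bands per lung (0.75) that arc in from the
lateral chest wall and penetrate about 40% of the lung width, three
vessel lines per lung (0.65) fanning out of the medial hilum to about 55%
of the lung width, and optional nodule discs (0.9) placed on a rib, on a
vessel, or free in the parenchyma. Geometry is jittered by +/-1% per
phantom; Gaussian noise (sigma 0.05) is the default corruption. Ground
truth masks cover every structure; the class label is Abnormal iff any
nodule exists, and the risk label is high iff a nodule is on a rib or has
radius >= 8 px.

Two geometric properties are load-bearing: rib bands and vessels never
sever the parenchyma (ribs stop short of the medial side, vessels stop
short of the lateral boundary), so a single grown region can reach a
whole quadrant; and each lung field is an ellipse, so its convex hull is
itself, which is what the hull-based extraction assumes.

What the phantom does **not** emulate: Hounsfield calibration, 3-D
anatomy, lesion texture, pleural attachment, imaging artifacts other than
additive Gaussian / Poisson noise, and anatomical variation beyond the 1%
jitter. Passing the phantom suite therefore demonstrates internal
correctness and end-to-end learnability of the pipeline, not clinical
performance.

## Problem sizes

The demo pipeline trains on 120 phantoms and evaluates on 60 (half
abnormal in both), sizes chosen so the engineered-feature classifier has
enough examples to generalize while a full run stays comfortable on a
laptop CPU. Denoising and segmentation quality are each measured on 10
seeded phantoms; the optimizer benchmark uses the 2-D sphere function
with `m = 20`, `Tn = 50`.

## Known limitations

* The gain convention makes diffusion strongest at strong edges, so long
  diffusion times erode structure; the package keeps the default time
  short rather than altering the gain's monotonicity.
* The on-rib flag `d_min < inter_rib` fires for most lung positions
  whenever two or more rib chains are visible in a quadrant — with
  anatomically spaced ribs, few points are farther from the nearest rib
  than the inter-rib distance. Risk screening consequently over-calls
  `high` for nodules that sit between ribs.
* Feature-vector convolutions see an arbitrary but fixed feature order;
  the fully connected head does most of the work, and the convolutional
  stem is kept for architectural fidelity rather than necessity.
* The chi-square selection with the default binomial significance level
  (R about 0.38) is deliberately liberal and admits a substantial noise
  fraction; the classifier's regularization is what copes with it.
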