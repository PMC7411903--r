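---
title: "Fuzzy clustering for breast-mass segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy clustering for breast-mass segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfcm)
```

## The problem

Masses in digital mammograms are bright, low-contrast regions embedded in
textured parenchyma, and the images are frequently corrupted by impulse
("salt-and-pepper") noise. The package implements a complete desk-scale
pipeline for this setting: intensity clustering to segment the lesion,
shape and texture descriptors of the segmented region of interest (ROI),
and a fuzzy-weighted support vector machine (FSVM) that classifies masses
as benign (round, smooth-margined) or malignant (irregular, spiculated).
Because the classical mammogram databases cannot be redistributed, the
package ships a seeded phantom generator that reproduces the *structure*
of such data — a bright lesion on textured tissue over a dark background,
with class-dependent boundary irregularity — so that every stage is
testable end to end.

## The clustering family

All four algorithms operate on the vector of pixel intensities
$x_l \in [0,1]$ and maintain $k$ cluster centers $v_m$ (default $k = 3$:
background, tissue, lesion). Squared Euclidean distances are written
$d_{lm}^2 = \lVert x_l - v_m \rVert^2$ and the fuzzifier is $p > 1$
(default 2).

**Fuzzy c-means (FCM).** Minimizes
$J = \sum_m \sum_l u_{lm}^p d_{lm}^2$ subject to $\sum_m u_{lm} = 1$, by
alternating

$$u_{lm} = \Big(\textstyle\sum_q (d_{lm}^2 / d_{lq}^2)^{1/(p-1)}\Big)^{-1},
\qquad
v_m = \frac{\sum_l u_{lm}^p x_l}{\sum_l u_{lm}^p}.$$

A point coincident with a center receives full membership there (ties
split equally). Iteration stops when
$\max |\Delta u| < \text{tol}$ (default $10^{-5}$) or after `max_iter`
(default 100) rounds; centers are initialized as $k$ points sampled
without replacement under a required, recorded seed.

**Possibilistic FCM (PFCM).** Drops the sum-to-one constraint; each
"typicality" reflects absolute closeness to a cluster,

$$u_{lm} = \frac{1}{1 + (d_{lm}^2/\lambda_m)^{1/(p-1)}},$$

which is the exact minimizer of
$\sum u^p d^2 + \sum_m \lambda_m \sum_l (1-u_{lm})^p$. The scales
$\lambda_m = W \sum_l u^p d^2 / \sum_l u^p$ (default $W = 1$) are
estimated **once** from a converged FCM run and then held fixed — letting
$\lambda$ float invites the trivial collapse $\lambda \to 0$, and a fixed
$\lambda$ makes the possibilistic phase a true alternating minimization.

**Intuitionistic FCM (IFCM).** Views each membership as an intuitionistic
fuzzy value with a nonmembership $\nu$ and a hesitation degree
$\pi = 1 - u - \nu$. The nonmembership generator is the Sugeno negation

$$\nu = \frac{1-u}{1 + \lambda_s u}, \qquad \lambda_s \ge 0
\;(\text{default } 2),$$

chosen because it guarantees $\pi \ge 0$ (the Yager class does not) and
makes $u + \nu + \pi = 1$ hold *exactly* in floating point by
construction. The lifted ("star") membership $u^* = u + \pi$ replaces $u$
in the center update. At $\lambda_s = 0$ the lift is the identity and the
trajectory is bit-for-bit the FCM one.

**Hybrid IPFCM.** FCM initialization, scale estimation, then a loop of
typicality update, Sugeno hesitation, star lift, and star-weighted center
update, converging on $\max|\Delta u^*|$. At $\lambda_s = 0$ it is
bit-for-bit PFCM.

### Scale-policy design note

The hybrid's published description can be read as rescaling $\lambda_m$
inside the loop with a star-lifted numerator. Both variants were
implemented and measured. Any star-lifted numerator inflates
$\lambda_m$ by the factor $\sum (u^*)^p d^2 / \sum u^p d^2 \ge 1$, and the
inflation is largest exactly for minority clusters; with it, the hybrid
failed even the one-dimensional outlier-recovery benchmark that plain
PFCM passes. The package therefore uses the same once-estimated, fixed
possibilistic scales for PFCM and IPFCM. This also makes the
$\lambda_s = 0$ reduction exact and keeps the objective trace meaningful.

### A negative result the tests assert honestly

Two properties one might expect of the hybrid are **false** for its
printed update scheme, and the acceptance tests that assert them fail by
design rather than being weakened:

1. *Objective descent.* The star lift $u^* = g(u)$ with
   $g(u) = u(1+\lambda_s)/(1+\lambda_s u)$ is applied *after* the
   typicality update, so the membership entering the objective is no
   longer the objective's minimizer and the hybrid has no Lyapunov
   function. On two-blob data the trace increases by up to $\sim 10^{-3}$
   on most seeds (FCM's trace, by contrast, is monotone to $10^{-9}$).
2. *Noise robustness on images.* $g$ amplifies small typicalities by
   $\approx (1+\lambda_s)$. For a minority cluster (the lesion occupies
   only a few percent of the image) the amplified far-field attraction of
   the large tissue mass exceeds the lesion's own pull, and the lesion
   center migrates onto the tissue mode — even on clean images. Under
   impulse noise the converged-FCM scale of the lesion cluster is further
   inflated (roughly $5$–$10\times$) by extreme pixels absorbed at high
   membership, which destabilizes plain PFCM too. In the package's
   20-seed phantom sweep the mean segmentation accuracies at 9% noise are
   approximately 0.93 (FCM), 0.93 (IFCM), 0.83 (PFCM), 0.70 (IPFCM),
   0.62 (Otsu); the hybrid's advantage reported on the original study
   data does not reproduce under its printed equations. The sweep is
   recomputed by `tests/testthat/test-acceptance.R` on every run.

Where the hybrid *does* behave as advertised is the regime the
possibilistic idea was designed for: tight clusters with a modest
fraction of impulse outliers and no extreme mass imbalance. On
two 45-point intensity blobs with 10% of points driven to the top gray
level, FCM's centers are dragged by more than 0.05 while IPFCM recovers
the clean-data centers to within 0.05 (also asserted by the acceptance
suite).

For practical segmentation work with this package, `method = "fcm"` (or
`"ifcm"`) is the recommended default; `"pfcm"`/`"ipfcm"` are faithful
reference implementations of the published scheme.

## Segmentation conventions

- Labels are the per-pixel argmax of the governing membership matrix,
  ties to the lowest cluster index.
- The ROI is the cluster with the highest center intensity; its largest
  8-connected component (minimum 9 pixels) becomes the lesion mask.
- The Otsu baseline maximizes between-class variance over a 256-bin
  histogram, ties to the lowest threshold; constant images are rejected.
- Segmentation accuracy against a ground-truth map is the pixel agreement
  maximized over label permutations (at most 8 labels), so it is
  invariant to cluster renumbering.

## ROI descriptors

Nine shape features and seven histogram-texture features are extracted
per ROI (16 numeric columns in the feature table, fixed order).

- **Radial profile.** 32 rays from the centroid; each boundary crossing
  is the 0.5 level of a $3\times 3$ box-averaged occupancy field, refined
  by linear interpolation between marching samples (quarter-pixel step).
  The smoothing regularizes the digitization staircase: a digitized disk
  of radius 20 then shows at most $\sim$0.3 px of radial wobble instead
  of $\sim$0.65 px. Normalized radial length nrl divides by the maximum;
  its statistics divide by the 32 sample count (scale invariance).
- **Perimeter.** Chain-code arc length from Moore boundary tracing
  (axial step 1, diagonal $\sqrt 2$). A raw count of boundary *pixels*
  scales as $\approx 7.9 r$ for a disk and would bias the circularity
  $C_r = 1 - 4\pi A_r / P_r^2$ to $\approx 0.36$ for *every* circle; with
  the chain-code length a disk's $C_r$ stays below 0.1, preserving the
  defining property that circles score near zero while spiculated masses
  score high. The shape factor is $S_r = P_r^2 / A_r$ ($4\pi$ for a
  circle).
- **NCPS.** Distance from the centroid to the darkest interior pixel,
  normalized by the equivalent radius $\sqrt{A_r/\pi}$ — a division by
  the raw area would carry units of 1/length.
- **Radial-length entropy and texture entropy** use base-2 logs with a
  leading minus ($0 \log 0 = 0$), so both are nonnegative.
- **Texture moments** are computed on gray levels rescaled to $[0,1]$
  (comparability across bit depths); skewness and kurtosis are raw third
  and fourth central moments, not standardized.
- **Boundary gradient**: mean over the 32 rays of the intensity
  difference between the boundary point and the point 10 px inward
  (clamped at the centroid for short rays).

## Fuzzy SVM

The classifier solves the standard soft-margin dual with per-sample box
constraints $0 \le \beta_m \le s_m C$: the fuzzy weight $s_m \in (0,1]$
scales how much slack a sample may claim, so mislabeled or outlying
samples cannot dominate the boundary. Weights decay linearly with the
distance to the class mean, $s_m = 1 - d_m/(r + \delta)$ with $r$ the
class radius and $\delta = 10^{-6}$; `weighting = FALSE` sets all
$s_m = 1$ and recovers the plain SVM. The kernel is Gaussian,
$J(y, y') = \exp(-\lVert y-y' \rVert^2 / 2\sigma^2)$.

The solver is a sequential-minimal-optimization loop with
maximal-violating-pair selection, deterministic given the input order,
iteration-capped at $10^5$ pair updates, solved to a KKT gap of
$10^{-8}$; the bias averages $z_m - f(y_m)$ over margin support vectors.
Features are standardized with training-set statistics; defaults
$C = 10$, $\sigma = 1$ on the standardized scale. Malignant maps to
$+1$, benign to $-1$; a decision value of exactly zero predicts $+1$.

## The phantom generator

`make_phantom()` emulates the structure of a screening-mammogram patch:
background level 0.12, a central tissue disk (radius $0.42 \times$ image
side) at 0.38, and a lesion at 0.38 + `contrast` (default 0.35), all
overlaid with smooth correlated texture (Gaussian-filtered white noise,
sd `texture_sd` = 0.05). The lesion's mean radius is drawn from
$[0.09, 0.15] \times$ size, keeping its area between about 2.5% and 7% of
the image. Benign lesions are near-circular ellipses (elongation up to
1.15, harmonic boundary ripple below 2%); malignant lesions carry 6–12
spicule harmonics with amplitudes up to $\sim$0.2 of the radius plus
extra in-lesion texture, so the class signal lives in boundary shape —
circularity, shape factor, nrl spread and entropy — exactly the features
the classifier consumes. Noise experiments corrupt a phantom with
salt-and-pepper impulses at an exact pixel count (`round(level/100 * N)`
pixels set to 0 or 1), or optionally with additive Gaussian noise.

What the generator does **not** emulate: pectoral muscle, film labels,
vascular/ductal structure, the intensity calibration of real
mammograms, and inter-patient variability. A green end-to-end test
therefore establishes that the pipeline machinery is correct and that
the features separate shape-coded classes — not clinical performance.

## Numerical conventions

- All randomness flows through explicit integer seeds; per-phantom and
  per-noise seeds are derived from a master seed, and refitting with the
  same seed is bitwise reproducible.
- Gray images live in $[0,1]$; filters reflect at borders; PGM I/O (P2
  and P5, 8/16-bit) is native, PNG requires the optional `png` package.
- Degenerate inputs fail loudly: constant images for Otsu, empty
  clusters in center updates, single-class training sets, masks below 9
  pixels.
- The feature CSV is written with 17 significant digits so round trips
  are exact to formatting precision.

## Known limitations

- The hybrid clustering instability discussed above.
- The permutation-based accuracy is exponential in the label count
  (capped at 8 labels).
- The radial profile takes the first boundary crossing per ray; deeply
  folded (non-star-shaped) masks are measured by their farthest crossing
  only when the centroid falls outside the mask.
- The SMO solver is dense and single-threaded — adequate for feature
  tables of hundreds of ROIs, not for large-scale learning.
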