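---
title: "Feature-based registration with geometric-invariant matching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based registration with geometric-invariant matching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(georeg)
```

# The problem

Registering two grayscale images — medical scans taken at different times,
remote-sensing frames, astronomical exposures — means estimating the
similarity transform (rotation $\alpha$, translation $(\Delta u, \Delta v)$,
optionally isotropic scale $s$) that maps one image's coordinates onto the
other's. Feature-based methods detect salient points in both images,
describe their neighbourhoods compactly, and match descriptions; the
transform is then fitted robustly to the surviving correspondences.

The approach implemented here targets the regimes where plain descriptor
matching breaks down: scenes with strong noise, high dynamic range, many
near-identical details, or — the hardest case — almost no texture at all, as
in star-field frames where every interest point looks like every other.
Its central idea is to use the *mutual geometry* of the retained keypoints
(the vector of distances from each point to all the others) as a second,
appearance-free description, and to let a progressive sample consensus
decide the final correspondence set.

# Pipeline

`registerImages()` runs seven stages; every stage's match table is kept on
the result object for inspection.

1. **Detection.** FAST-9 segment test on each pyramid level: a pixel is a
   corner candidate when at least 9 contiguous of the 16 pixels on its
   radius-3 Bresenham circle are all brighter or all darker than the
   centre by more than $\xi$ (default 40). The whole-circle sum of
   absolute differences serves as the candidate response for a 3×3
   non-maximum suppression; the Harris corner response
   $\det(M) - k\,\mathrm{tr}(M)^2$ (Sobel gradients, 7×7 Gaussian window
   with $\sigma = 1.5$, $k = 0.04$) selects the strongest candidates.
   Each keypoint's dominant orientation is the intensity-centroid angle
   $\alpha = \mathrm{atan2}(M_{01}, M_{10})$ over a radius-15 circular
   patch.
2. **Description.** A 256-pair sampling pattern (isotropic Gaussian,
   $\sigma = $ patch half/2, clipped to the patch disk; fixed seed 42 for
   reproducibility) is steered by the keypoint orientation and each pair
   compares 5×5 box sums (integral image) around its two sample points;
   bit = 1 iff the first sum is strictly smaller. Steered patterns are
   cached at 30 discrete angles (12° bins) so descriptors are
   deterministic; exact per-angle steering is available. A greedy
   de-correlation learner (`learnPatternGreedy()`) is provided for users
   with a training corpus.
3. **Initial matching.** Brute-force Hamming matching: every query
   descriptor is paired with its nearest train descriptor. This is the
   "initial matching points" count.
4. **Scale screening.** Keypoints are detected on a Gaussian pyramid
   (factor 2, up to 4 levels, anti-alias $\sigma = 0.5 \cdot$ factor); a
   match's scale ratio is the ratio of its endpoints' level scales. A
   histogram of ratios on log-spaced bins locates the dominant ratio;
   matches outside a $\pm\omega$ window (default 0.25, within the
   recommended 0.20–0.35) around the peak are rejected, the dominant
   ratio $d$ is re-estimated as the surviving mean, and only ratios in
   $[0.6d, 1.4d]$ are retained.
5. **Rough selection.** The Hamming-distance window
   $[\bar D - \epsilon_1, \bar D + \epsilon_2]$ with
   $\epsilon_1 = (\bar D - D_{min})/2$, $\epsilon_2 = (D_{max} - \bar D)/2$
   (the midpoint reading of "medium value") removes both suspiciously
   similar and clearly dissimilar pairs; a bidirectional KNN ratio test
   (optimal/sub-optimal $< t = 0.65$, both directions, mutual nearest
   neighbours) retains the unambiguous pairs.
6. **Geometric-invariant matching.** For each image, the retained
   keypoints form a constellation; each point's *distance profile* is the
   ascending vector of its Euclidean distances to all other retained
   points. Profiles are compared with the Gaussian similarity
   $F_{i,j} = \sum_s \sum_t \exp(-(D_i(s) - D_j(t))^2 / \sigma^2)$
   (default $\sigma = 1$ px) and a candidate is accepted when the
   runner-up similarity is below $T = 0.8$ of the best.
7. **Consensus.** PROSAC: candidates sorted by geometric distinctiveness;
   each iteration draws three pairs uniformly from the current top-$\eta$
   prefix plus the $\eta$-th pair ($\eta$ starts at 4, grows by one per
   iteration), fits the transform in closed form (Procrustes), and counts
   inliers under $\|Mp - p'\|^2 \le \tau_{in}$ (default 9 px², i.e. a
   3 px residual). Sampling stops when the inlier fraction exceeds 0.5,
   when the best inlier count grows slower than 0.1/iteration over a
   10-iteration window, or at the iteration cap. The final transform is
   re-fitted on the consensus set.

# Design decisions in detail

## Kernel sign and profile units

The similarity kernel is implemented as $\exp(-\Delta^2/\sigma^2)$; the
positive-exponent variant is retained behind `mode = "as-printed"` for
audit, but it is unbounded, scores larger discrepancies *higher*, and
makes the runner-up ratio test vacuous (the ratio of best to anything is
then always ≥ 1), so it cannot drive a selective matcher.

Profiles default to **raw pixel distances** with $\sigma = 1$ px. The
alternative (profiles normalized by their own mean, same $\sigma$)
saturates on clean constellations: normalized distances concentrate near
1, every pairwise term contributes $\approx e^{-\Delta^2} \approx$ 0.6–1,
and the runner-up ratio approaches 1.0 for every candidate, so nothing
passes $T = 0.8$ — the test suite characterizes this directly (raw
profiles recover 100/100 clean constellations; normalized profiles at
$\sigma = 1$ emit no matches on the same inputs). The kernel
width is a *distance error tolerance*, and it is only meaningful in the
units the error lives in — pixels. Normalized profiles remain available
(`normalizeProfiles = TRUE`) for scale-varying point sets, with the
guidance that $\sigma$ should then be of the order of the relative
position jitter (≈ 0.02), not 1. Scale variation between images is
handled upstream by the pyramid and the scale-ratio screen, so raw
profiles are appropriate at the geometric stage.

## Steering orientation

The pattern-rotation matrix is applied as printed in `steerPattern()`
(at $\alpha = \pi/2$: $(x, y) \mapsto (y, -x)$). Combined with
$\alpha = \mathrm{atan2}(M_{01}, M_{10})$ in y-down pixel coordinates,
that matrix rotates the pattern *against* the content: if the patch
content rotates by $\varphi$ (so the centroid angle becomes
$\alpha + \varphi$), sampling at $R(-\alpha-\varphi)\,q$ lands on
$R(-\alpha-2\varphi)\,q$ of the original content — not covariant. The
descriptor therefore steers by the *inverse* angle internally, sampling
at $R(+\alpha)\,q$, which reproduces the unrotated descriptor exactly in
the continuum limit. The rotation-covariance tests (median Hamming
distance ≤ 40/256 across a 30° rotation) pin this choice down; the
literal pairing is not covariant, so under it the steered samples stop
tracking the content as soon as the view rotates.

## Stage pools and nesting

The geometric matcher *re-pairs* keypoints rather than filtering existing
pairs, so its pool construction matters:

* **Query pool:** endpoints of the scale-stage matches.
* **Train pool:** the nearest *and* second-nearest train keypoints of
  each pooled query. In sparse scenes several queries share one nearest
  neighbour; with a nearest-only pool the displaced true counterparts
  never enter the constellation and can never be recovered.
* Pools are deduplicated at a 2 px radius preferring the finest pyramid
  level (coarser levels carry ±(scale/2) px coordinate quantization) and
  capped at `geomMaxPoints` (default 80) by Harris response, because the
  profile cost is quadratic in the product of pool sizes.
* The full greedy one-to-one assignment on the cost matrix forms the
  *candidate list*; the distinctiveness test ($T$) defines the reported
  geometric stage; PROSAC samples from the quality-sorted prefix of the
  candidate list but counts consensus over all of it. This is the
  published progressive-consensus formulation — the sample set is the
  high-quality prefix, the consensus is evaluated on every tentative
  correspondence — and it is what lets star-field scenes reach a full
  consensus when the ratio tests alone would keep only a handful of
  pairs.

Pair-nesting consequently holds through the bidirectional stage
(initial ⊇ scale ⊇ window ⊇ bidirectional); the geometric stage's queries
come from the scale stage, and the prosac stage is a subset of the
geometric candidate list. `RegistrationResult`'s validity method enforces
exactly this.

## Initial matching definition

"Initial matching points" counts plain brute-force nearest-neighbour
pairs (one per query keypoint), not mutual-nearest pairs: published
counts of ≈ 486 initial matches from ≈ 500 keypoints are only consistent
with per-query matching, and mutual consistency belongs to the
bidirectional stage, where it is part of the method proper.

## Parameters

| key | default | units | meaning |
|---|---|---|---|
| `xiFast` | 40 | intensity | FAST segment-test threshold |
| `nFeatures` | 500 | count | keypoints kept per image (area-weighted across levels) |
| `pyramidLevels`, `pyramidFactor` | 4, 2 | — | pyramid depth and per-level ratio |
| `omega` | 0.25 | ratio | scale-ratio window half-width (recommended 0.20–0.35) |
| `t` | 0.65 | — | bidirectional KNN ratio threshold |
| `sigma` | 1 | px | geometric kernel width (distance error tolerance) |
| `T` | 0.8 | — | distinctiveness threshold (runner-up/best) |
| `K` | 2 | count | ranked candidates examined (second-best test) |
| `eta0` | 4 | count | initial PROSAC prefix size |
| `tauIn` | 9 | px² | squared-residual inlier bound (3 px) |
| `tauRatio`, `tauGrow`, `patience` | 0.5, 0.1, 10 | — | termination: inlier fraction / growth rate / window |
| `geomMaxPoints` | 80 | count | geometric pool cap per image |
| `tolPx` | 3 | px | ground-truth correctness tolerance in evaluation |

A single symbol served several of these roles in the original
presentation (the FAST threshold, the inlier bound and the inlier-ratio
threshold are all written $\xi$ there); they are deliberately split into
distinct keys. $\eta_0 = 4$ is kept although the similarity fit needs
only 2 pairs: over-determined minimal samples are more stable.

# Synthetic data: what it emulates, and what it does not

`synthTexturePair()` emulates textured scenes under rotation and
illumination change: band-limited noise plus randomly placed rotated
rectangles (corner-rich), warped bilinearly by the ground-truth
transform, then subjected to gain/offset and additive Gaussian noise.
`synthStarfieldPair()` emulates the low-texture/high-dynamic-range
regime: a near-black noise floor and Gaussian point-spread spots whose
peaks are log-spread over the dynamic range (most stars are therefore
*undetectable* at an 8-bit contrast threshold — deliberately, since that
is what makes the scenario hard); image B is rendered as an independent
exposure at the transformed star positions rather than by resampling
image A, because bilinear resampling would dim sub-pixel peaks by up to
20%, a systematic error no real second exposure has.
`synthCorrespondences()` provides labelled point sets with controlled
outlier fraction and noise for the consensus modules. All generators are
pure functions of their arguments and restore the session RNG.

What passing tests on these fixtures does **not** show: robustness to
non-rigid deformation (the model is similarity-class only), to
photometric nonlinearities beyond gain/offset, to structured sensor
noise, or to real anatomical/astronomical content statistics. The
published end-to-end screening counts were measured on images that are
not distributed with their article; this package reproduces their metric
*arithmetic* exactly (all 12 benchmark rates from their counts) but makes
no claim of reproducing those counts on unavailable images.

# Numerical and degenerate-case choices

* Histogram bins for scale ratios: 32 log-spaced bins over the observed
  range, inflated to a minimum 5% ratio width; peak ties break toward
  ratio 1; the window applies to the peak bin's centre.
* Distance-window: inclusive on both ends; all-equal distances collapse
  the window to a point and retain everything.
* KNN ties break toward the lower index; a duplicate second-nearest at
  distance 0 gives ratio 1 (ambiguous, rejected for $t < 1$); a
  single-descriptor side has no competitor and passes by convention.
* Descriptor comparisons are strict (`<`); ties produce bit 0, so a
  constant image gives the all-zero descriptor.
* Point-symmetric orientation patches ($M_{01} = M_{10} = 0$) get
  $\alpha = 0$.
* Coincident points are a degenerate-geometry error for profiles;
  coincident source points are a degenerate-input error for the fit. A
  reflective correspondence yields the best *proper* rotation with large
  residuals (exposed via `transformResiduals()`), never an improper one.
* The consensus loop skips degenerate minimal samples (coincident
  points) without consuming the candidate's chance; final inlier flags
  are recomputed under the re-fitted transform, so every flagged inlier
  provably satisfies the bound.
* Evaluation rates round half-up to two decimals, matching the published
  presentation of matching rates.

# Problem sizes and determinism

The shipped tests and the acceptance script use 256×256 (pipeline
scenarios) and 128–192 px (module tests) images, 20 seeds for texture
recovery, 10 for star fields, 30 for consensus robustness, and 100 clean
constellations for matcher exactness — sizes at which every stage,
including the exhaustive brute-force oracles, completes in seconds while
leaving the statistics stable. All randomness flows through explicit
seeds; `registerImages()` is deterministic given `config$seed`, and every
generator restores the caller's RNG state.

# Known limitations

* The transform family is similarity-class; affine shear, projective
  effects and non-rigid deformation are out of scope.
* Sub-pixel keypoint refinement is deliberately absent; localization is
  integer-pixel at each level, so coarse-level detections carry
  ±(scale/2) px quantization (mitigated by the finest-level preference in
  the geometric pool).
* The descriptor's rotation covariance is approximate (quantized
  steering, integer sampling): expect a floor of ≈ 15–25/256 Hamming
  between rotated views of the same point.
* In scenes with fewer than ~10 detectable features shared between the
  images, no screening design can produce a larger consensus; the
  pipeline returns the partial result with its termination stage rather
  than guessing.
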