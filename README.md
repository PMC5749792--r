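# georeg

Feature-based registration of 2-D grayscale image pairs — medical scans,
remote-sensing frames, astronomical exposures — built for the regimes where
plain descriptor matching fails: strong noise, high dynamic range, many
near-identical details, or almost no texture at all.

## What it does

`georeg` estimates the similarity transform

$$\begin{bmatrix}u\\v\\1\end{bmatrix} =
\begin{bmatrix} s\cos\alpha & -s\sin\alpha & \Delta u\\
                s\sin\alpha & \phantom{-}s\cos\alpha & \Delta v\\
                0 & 0 & 1\end{bmatrix}
\begin{bmatrix}u'\\v'\\1\end{bmatrix}$$

between an image pair through a staged pipeline:

1. **FAST-9 corners** (9 contiguous of 16 circle pixels differing from the
   centre by more than $\xi = 40$) with Harris-response selection
   ($\det M - 0.04\,\mathrm{tr}^2 M$) and intensity-centroid orientation
   $\alpha = \mathrm{atan2}(M_{01}, M_{10})$, on a Gaussian image pyramid.
2. **Steered 256-bit BRIEF descriptors** comparing 5×5 box-sum
   sub-windows, matched brute-force by Hamming distance
   $D = \mathrm{popcount}(hd_1 \oplus hd_2)$.
3. **Scale-ratio histogram screening**: matches outside a $\pm\omega$
   window around the dominant pyramid-scale ratio $d$, or outside
   $[0.6d, 1.4d]$, are rejected.
4. **Rough selection**: a mean-centred distance window
   $[\bar D - (\bar D - D_{min})/2,\; \bar D + (D_{max} - \bar D)/2]$ and a
   bidirectional KNN ratio test ($D_1/D_2 < t = 0.65$, both directions,
   mutual).
5. **Geometric-invariant matching** — the distinctive part: each surviving
   keypoint is described by its *distance profile* $D_i(n) = \lVert p_i -
   p_j\rVert_2$ to all other retained points, profiles are compared with
   the Gaussian similarity
   $F_{i,j} = \sum_s\sum_t \exp\!\big({-[D_i(s) - D_j(t)]^2}/{\sigma^2}\big)$
   ($\sigma = 1$ px), and a pair is accepted when the runner-up similarity
   is below $T = 0.8$ of the best. This matches constellations, not
   appearances, so it works where every feature looks alike.
6. **PROSAC** consensus: quality-sorted progressive sampling (initial
   sample size $\eta = 4$), closed-form Procrustes fits, inlier rule
   $\lVert Mp - p'\rVert^2 \le \tau_{in}$, final re-fit on the consensus
   set.

Deterministic synthetic fixture generators (textured scenes, star fields,
labelled correspondences with known transforms) make every stage testable
against ground truth without any external data.

## Worked example

Register a synthetic textured pair whose ground truth is a 30° rotation
about the image centre plus a (12, −7) px translation, with noise:

```r
library(georeg)
truth <- similarityAbout(c(127.5, 127.5), 30 * pi / 180, translation = c(12, -7))
fix   <- synthTexturePair(1, size = 256, transform = truth, noiseSigma = 2)
res   <- registerImages(fix@imageA, fix@imageB)
res
#> RegistrationResult
#>   keypoints: 302 (A), 300 (B)
#>   initial       302 match(es)
#>   scale         275 match(es)
#>   window        192 match(es)
#>   bidirectional 86 match(es)
#>   geometric     35 match(es)
#>   prosac        66 match(es)
#> SimilarityTransform: alpha 0.5239 rad (30.02 deg), t = (92.943, -53.607), s = 0.99942

evaluateMatches(res, fixtureTruth(fix))
#> MatchMetrics: 302 initial, 66 screened, 0 mismatch(es), rate 100.00%
```

Reading the output: 302 initial brute-force Hamming pairs are screened to
275 (scale-consistent), 192 (distance window), 86 (bidirectional ratio
test); the geometric matcher accepts 35 distinctive constellation pairs
and PROSAC's consensus over the full candidate list settles on 66
correspondences. The recovered transform (30.02°, translation column
(92.94, −53.61), scale 0.99942) matches the ground-truth matrix (30.00°,
(92.83, −53.67), 1) to within 0.02° and 0.12 px; all 66 screened matches
are correct within 3 px, a 100.00% matching rate.

The per-stage tables stay on the result (`stageMatches(res, "window")`,
…), diagnostics include the scale histogram and distance window, and
`writeResultJSON()` / `writeKeypointCSV()` / `writeTransformJSON()`
serialize everything to plain text. A command-line wrapper lives at
`inst/scripts/georeg-cli.R` (`register`, `simulate`, `eval` subcommands).

## Documentation

The methods vignette (`vignettes/registration-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, the design decisions behind the kernel sign, profile units,
steering orientation and stage pooling, what the synthetic generators do
and do not emulate, and the package's known limitations.
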