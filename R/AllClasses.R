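#' @import methods
NULL

#' GrayImage: 2-D 8-bit-range intensity raster
#'
#' A \code{GrayImage} is a numeric matrix of intensities in \eqn{[0, 255]},
#' indexed \code{[row, col]} with the origin at the top-left. Pixel
#' coordinates used throughout the package are 0-based with \code{x} the
#' column and \code{y} the row, so intensity at \code{(x, y)} is
#' \code{img[y + 1, x + 1]}. Values need not be integers (synthetic star
#' fields use sub-unit intensities to realise a high dynamic range).
#'
#' @slot .Data numeric matrix of intensities in \eqn{[0, 255]}.
#' @seealso [GrayImage()], [readGrayImage()]
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
  px <- object@.Data
  if (!is.numeric(px) || length(dim(px)) != 2L)
    return("pixels must be a 2-D numeric matrix")
  if (anyNA(px))
    return("pixels must not contain NA")
  if (min(px) < 0 || max(px) > 255)
    return("all intensities must lie in [0, 255]")
  TRUE
})

#' SamplingPattern: point pairs for the binary descriptor
#'
#' Holds the 256 (or, for learned sub-selections, \code{k}) point pairs of
#' the sub-window BRIEF test, in patch-centred integer pixel offsets
#' (x right, y down). The 2 x N stack of all pattern point coordinates is
#' the matrix rotated when the pattern is steered by a keypoint orientation.
#'
#' @slot pairs integer matrix with columns \code{mx, my, nx, ny}, one row
#'   per binary test.
#' @slot patchHalf integer, half-size of the square descriptor patch.
#' @export
setClass("SamplingPattern",
  representation(pairs = "matrix", patchHalf = "integer"),
  validity = function(object) {
    p <- object@pairs
    if (ncol(p) != 4L) return("pairs must have columns mx,my,nx,ny")
    if (any(abs(p) > object@patchHalf))
      return("pattern coordinates exceed the patch half-size")
    TRUE
  })

#' BinaryDescriptors: a set of 256-bit descriptors
#'
#' Bits are stored as a 256 x n integer matrix of 0/1; column \code{i} is
#' the descriptor of keypoint \code{i}, bit order equals pattern pair order.
#'
#' @slot bits integer matrix (256 rows, one column per descriptor).
#' @export
setClass("BinaryDescriptors",
  representation(bits = "matrix"),
  validity = function(object) {
    b <- object@bits
    if (nrow(b) != 256L) return("descriptors must be exactly 256 bits")
    if (length(b) && !all(b %in% c(0L, 1L))) return("bits must be 0/1")
    TRUE
  })

#' SimilarityTransform: rotation + translation (+ isotropic scale)
#'
#' Maps source coordinates \code{(u', v')} to \code{(u, v)} by
#' \deqn{p = s R(\alpha) p' + (\Delta u, \Delta v)} with
#' \eqn{R(\alpha) = [[\cos\alpha, -\sin\alpha], [\sin\alpha, \cos\alpha]]}
#' acting on (x, y-down) pixel coordinates. With \code{s = 1} this is the
#' rigid rotation-translation family used for consensus estimation.
#'
#' @slot alpha rotation angle in radians.
#' @slot du,dv translation in pixels (x and y).
#' @slot s isotropic scale factor (> 0).
#' @seealso [similarityTransform()], [transformMatrix()], [applyTransform()]
#' @export
setClass("SimilarityTransform",
  representation(alpha = "numeric", du = "numeric", dv = "numeric", s = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != 1L || length(object@du) != 1L ||
        length(object@dv) != 1L || length(object@s) != 1L)
      return("alpha, du, dv, s must be scalars")
    if (!is.finite(object@s) || object@s <= 0) return("scale s must be > 0")
    TRUE
  })

#' ImagePyramid: Gaussian low-pass pyramid of a GrayImage
#'
#' @slot levels list of \linkS4class{GrayImage}, level 1 being the input.
#' @slot scale nominal cumulative downsampling factor per level.
#' @slot scaleX,scaleY actual per-axis factors (level-0 extent / level extent),
#'   used to map keypoints back to level-0 coordinates.
#' @export
setClass("ImagePyramid",
  representation(levels = "list", scale = "numeric",
                 scaleX = "numeric", scaleY = "numeric"),
  validity = function(object) {
    n <- length(object@levels)
    if (length(object@scale) != n || length(object@scaleX) != n ||
        length(object@scaleY) != n)
      return("scale vectors must match the number of levels")
    if (n && any(object@scale < 1)) return("cumulative scales must be >= 1")
    TRUE
  })

#' ScaleHistogram: histogram of match scale ratios
#'
#' Diagnostic record of the scale-ratio screening: log-spaced bins, the peak
#' bin, the ratio window half-width and the dominant ratio \code{d} whose
#' \code{[0.6 d, 1.4 d]} band defines the final retention rule.
#'
#' @slot breaks numeric bin edges (ratio units, log-spaced).
#' @slot counts integer bin counts.
#' @slot peakBin index of the peak bin (0 when the histogram is empty).
#' @slot omega window half-width in ratio units.
#' @slot dominantRatio the dominant scale ratio \code{d} (NA when empty).
#' @export
setClass("ScaleHistogram",
  representation(breaks = "numeric", counts = "integer", peakBin = "integer",
                 omega = "numeric", dominantRatio = "numeric"),
  validity = function(object) {
    if (length(object@counts) &&
        length(object@breaks) != length(object@counts) + 1L)
      return("breaks must be one longer than counts")
    TRUE
  })

#' DistanceWindow: mean-centred Hamming distance selection window
#'
#' The window is \eqn{[\bar D - \epsilon_1, \bar D + \epsilon_2]} with
#' \eqn{\epsilon_1 = (\bar D - D_{min})/2} and
#' \eqn{\epsilon_2 = (D_{max} - \bar D)/2} (midpoint reading of the
#' "medium value" between the extremes and the mean).
#'
#' @slot dBar mean Hamming distance.
#' @slot eps1,eps2 lower/upper half-widths (>= 0; 0 only in the degenerate
#'   all-equal case, where every match is retained).
#' @export
setClass("DistanceWindow",
  representation(dBar = "numeric", eps1 = "numeric", eps2 = "numeric"),
  validity = function(object) {
    if (object@eps1 < 0 || object@eps2 < 0) return("eps1/eps2 must be >= 0")
    TRUE
  })

#' DistanceProfileSet: geometric-invariant distance profiles
#'
#' Profile \code{i} holds the Euclidean distances (level-0 pixels) from
#' point \code{i} to every other retained point of the same image, sorted
#' ascending. Profiles are invariant under rigid motions; when normalized
#' (each divided by its own mean) they are invariant under similarity
#' transforms.
#'
#' @slot profiles list of ascending numeric vectors, one per point.
#' @slot normalized logical flag.
#' @slot normFactors per-profile mean distance (1 when not normalized).
#' @export
setClass("DistanceProfileSet",
  representation(profiles = "list", normalized = "logical",
                 normFactors = "numeric"),
  validity = function(object) {
    if (length(object@profiles) != length(object@normFactors))
      return("one norm factor per profile required")
    if (any(vapply(object@profiles, function(p) any(p <= 0), logical(1))))
      return("all profile distances must be > 0")
    if (object@normalized &&
        any(vapply(object@profiles,
                   function(p) abs(mean(p) - 1) > 1e-8, logical(1))))
      return("normalized profiles must have mean 1")
    TRUE
  })

#' ConsensusResult: outcome of progressive/random sample consensus
#'
#' @slot transform the final \linkS4class{SimilarityTransform}, re-fitted on
#'   all inliers.
#' @slot inliers logical flag per input match; every flagged inlier satisfies
#'   the squared-residual bound under \code{transform}.
#' @slot nIterations number of sampling iterations executed.
#' @slot termination one of \code{"ratio"}, \code{"growth"}, \code{"max_iter"}.
#' @slot history best inlier count after each iteration.
#' @slot tauIn the squared-residual inlier bound used (pixels^2).
#' @export
setClass("ConsensusResult",
  representation(transform = "ANY", inliers = "logical",
                 nIterations = "integer", termination = "character",
                 history = "integer", tauIn = "numeric"),
  validity = function(object) {
    if (!object@termination %in% c("ratio", "growth", "max_iter"))
      return("unknown termination reason")
    TRUE
  })

#' MatchMetrics: screening metrics for a registration run
#'
#' The matching rate is \eqn{100 (n_{screened} - n_{mismatch})/n_{screened}}
#' (0 by convention when nothing survives screening), rounded half-up to two
#' decimals.
#'
#' @slot nInitial initial matching points (mutual-nearest Hamming pairs).
#' @slot nScreened matching points after screening.
#' @slot nMismatch mismatches after screening (against ground truth).
#' @slot rate matching rate in percent.
#' @export
setClass("MatchMetrics",
  representation(nInitial = "integer", nScreened = "integer",
                 nMismatch = "integer", rate = "numeric"),
  validity = function(object) {
    if (object@nMismatch > object@nScreened)
      return("mismatches cannot exceed screened matches")
    if (object@nInitial >= 0 && object@nScreened > object@nInitial)
      return("screened matches cannot exceed initial matches")
    TRUE
  })

#' FixturePair: synthetic image pair with known ground truth
#'
#' @slot imageA,imageB \linkS4class{GrayImage} pair.
#' @slot truth \linkS4class{SimilarityTransform} mapping image-A coordinates
#'   to image-B coordinates.
#' @slot meta list: seed, scenario tag, noise sigma, gain/offset, etc.
#'   Regenerating with the same meta reproduces identical images.
#' @export
setClass("FixturePair",
  representation(imageA = "GrayImage", imageB = "GrayImage",
                 truth = "SimilarityTransform", meta = "list"))

#' RegistrationResult: full per-stage record of a registration run
#'
#' Stage match tables are kept in pipeline order: \code{initial},
#' \code{scale}, \code{window}, \code{bidirectional}, \code{geometric},
#' \code{prosac}. Consecutive pair-nesting holds through the bidirectional
#' stage; the geometric stage re-pairs the scale-consistent keypoints by
#' constellation similarity, so its query endpoints come from the scale
#' stage while its train endpoints come from those queries' KNN candidate
#' set (its pairs are additionally nested in the bidirectional stage when
#' \code{intersectGeom = TRUE}). The prosac stage is the consensus subset
#' of the geometric candidate list (stored in
#' \code{diagnostics$geometricCandidates}), whose quality-sorted prefix
#' drives the progressive sampling.
#'
#' @slot keypointsA,keypointsB keypoint tables (columns \code{x, y, level,
#'   scale, response, orientation}, level-0 0-based pixel coordinates).
#' @slot stages named list of match tables (columns \code{queryIdx,
#'   trainIdx, hamming, scaleRatio, quality, stage}).
#' @slot transform final \linkS4class{SimilarityTransform} or NULL.
#' @slot consensus \linkS4class{ConsensusResult} or NULL.
#' @slot diagnostics list (scale histogram, distance window, stage counts).
#' @slot terminated name of the stage that emptied the match set
#'   (\code{"none"} on full success).
#' @slot config the configuration list used.
#' @export
setClass("RegistrationResult",
  representation(keypointsA = "data.frame", keypointsB = "data.frame",
                 stages = "list", transform = "ANY", consensus = "ANY",
                 diagnostics = "list", terminated = "character",
                 config = "list"),
  validity = function(object) {
    st <- object@stages
    pairKey <- function(m) paste(m$queryIdx, m$trainIdx)
    chain <- c("initial", "scale", "window", "bidirectional")
    for (i in seq_len(length(chain) - 1L)) {
      a <- st[[chain[i]]]; b <- st[[chain[i + 1L]]]
      if (!is.null(a) && !is.null(b) && nrow(b) &&
          !all(pairKey(b) %in% pairKey(a)))
        return(sprintf("stage '%s' is not a subset of stage '%s'",
                       chain[i + 1L], chain[i]))
    }
    g <- st[["geometric"]]; sc <- st[["scale"]]; p <- st[["prosac"]]
    if (!is.null(g) && !is.null(sc) && nrow(g) &&
        !all(g$queryIdx %in% sc$queryIdx))
      return("geometric stage queries must come from the scale stage")
    cand <- object@diagnostics[["geometricCandidates"]]
    pool <- if (!is.null(cand)) cand else g
    if (!is.null(p) && !is.null(pool) && nrow(p) &&
        !all(pairKey(p) %in% pairKey(pool)))
      return("prosac stage is not drawn from the geometric candidate set")
    TRUE
  })
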