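# Deterministic synthetic fixtures: textured scenes, low-texture star
# fields, labelled point correspondences. All generators are pure functions
# of their arguments (seeded locally; the session RNG is untouched).

#' Warp a GrayImage by a similarity transform
#'
#' Inverse-maps every output pixel through \code{solve(transform)} and
#' samples the source bilinearly, with constant zero padding outside the
#' frame. Coordinates follow the package convention (0-based, x = column,
#' y = row), so a point \code{p} of the source lands at
#' \code{applyTransform(transform, p)} in the output.
#'
#' @param image source \linkS4class{GrayImage}.
#' @param transform a \linkS4class{SimilarityTransform} (source to output
#'   coordinates).
#' @param outDim output c(height, width) (default: source dimensions).
#' @return the warped \linkS4class{GrayImage}.
#' @export
warpImage <- function(image, transform, outDim = dim(image)) {
  P <- image@.Data
  h <- nrow(P); w <- ncol(P)
  oh <- outDim[1]; ow <- outDim[2]
  inv <- solve(transform)
  gx <- rep(0:(ow - 1L), each = oh)
  gy <- rep(0:(oh - 1L), times = ow)
  src <- applyTransform(inv, cbind(gx, gy))
  x0 <- floor(src[, 1]); y0 <- floor(src[, 2])
  fx <- src[, 1] - x0; fy <- src[, 2] - y0
  at <- function(xx, yy) {
    ok <- xx >= 0 & xx <= w - 1L & yy >= 0 & yy <= h - 1L
    v <- numeric(length(xx))
    v[ok] <- P[cbind(yy[ok] + 1L, xx[ok] + 1L)]
    v
  }
  v <- (1 - fx) * (1 - fy) * at(x0, y0) + fx * (1 - fy) * at(x0 + 1, y0) +
       (1 - fx) * fy * at(x0, y0 + 1) + fx * fy * at(x0 + 1, y0 + 1)
  clampGrayImage(matrix(v, oh, ow))
}

# fraction of the output frame covered by the warped source frame
.coverage <- function(transform, h, w) {
  n <- 33L
  gx <- seq(0, w - 1L, length.out = n)
  gy <- seq(0, h - 1L, length.out = n)
  pts <- applyTransform(transform, cbind(rep(gx, each = n), rep(gy, n)))
  mean(pts[, 1] >= 0 & pts[, 1] <= w - 1 & pts[, 2] >= 0 & pts[, 2] <= h - 1)
}

#' Synthetic textured image pair with known ground truth
#'
#' Image A is band-limited noise (white noise smoothed with a Gaussian)
#' overlaid with randomly placed rotated rectangles of contrasting
#' intensity — a corner-rich scene. Image B is A warped by
#' \code{transform} (bilinear), subjected to the photometric change
#' \code{clip(gain * I + offset)} and additive Gaussian noise. Emulates
#' textured registration scenes with large rotation and varying
#' illumination.
#'
#' @param seed integer seed; identical arguments reproduce identical pairs.
#' @param size image side in pixels (>= 128, default 256).
#' @param transform ground-truth \linkS4class{SimilarityTransform} mapping
#'   A to B coordinates (default identity).
#' @param noiseSigma additive Gaussian noise sigma on image B (default 0).
#' @param gain,offset photometric change applied to image B (defaults 1, 0;
#'   gain must be > 0).
#' @param nBlobs number of rectangles (default 30).
#' @return a \linkS4class{FixturePair}.
#' @export
synthTexturePair <- function(seed, size = 256L, transform = similarityTransform(),
                             noiseSigma = 0, gain = 1, offset = 0,
                             nBlobs = 30L) {
  if (size < 128L) stop("size must be >= 128", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (.coverage(transform, size, size) < 0.1)
    stop("transform pushes nearly all content out of frame", call. = FALSE)
  imgA <- withSeed(seed, {
    base <- matrix(stats::rnorm(size * size), size, size)
    base <- EBImage::gblur(base, sigma = 1.5)
    base <- (base - min(base)) / (max(base) - min(base)) * 120 + 60
    X <- matrix(rep(0:(size - 1L), each = size), size)
    Y <- matrix(rep(0:(size - 1L), times = size), size)
    for (b in seq_len(nBlobs)) {
      cx <- stats::runif(1, 20, size - 21)
      cy <- stats::runif(1, 20, size - 21)
      th <- stats::runif(1, 0, pi)
      aH <- stats::runif(1, 6, 22); bH <- stats::runif(1, 6, 22)
      val <- sample(c(-1, 1), 1) * stats::runif(1, 50, 110)
      u <- (X - cx) * cos(th) + (Y - cy) * sin(th)
      v <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
      m <- abs(u) <= aH & abs(v) <= bH
      base[m] <- base[m] + val
    }
    clampGrayImage(base)
  })
  imgB <- warpImage(imgA, transform)
  imgB <- withSeed(seed + 1000003L, {
    clampGrayImage(gain * imgB@.Data + offset +
                   stats::rnorm(length(imgB), 0, noiseSigma))
  })
  new("FixturePair", imageA = imgA, imageB = imgB, truth = transform,
      meta = list(scenario = "texture", seed = seed, size = size,
                  noiseSigma = noiseSigma, gain = gain, offset = offset,
                  nBlobs = nBlobs))
}

#' Synthetic star-field image pair (low texture, high dynamic range)
#'
#' A dark background with a faint noise floor and \code{nStars} Gaussian
#' point-spread spots whose peak intensities are log-spread over
#' \code{dynRange}; stars are rejection-placed at least \code{6 * psfSigma}
#' apart so each is an isolated local maximum. Image B is rendered as an
#' independent exposure of the same sky: the point-spread functions are
#' re-imaged at the transformed star positions (with a fresh noise floor
#' and optional additive noise) rather than resampled from image A, which
#' would systematically dim sub-pixel peaks. Emulates astronomical frames
#' with almost no texture but a high dynamic range.
#'
#' @param seed integer seed.
#' @param size image side (default 256).
#' @param nStars number of stars (>= 10, default 80).
#' @param dynRange ratio between the brightest and faintest star peaks
#'   (default 1000).
#' @param transform ground-truth transform A to B (default identity).
#' @param noiseSigma additive noise sigma on image B (default 0).
#' @param psfSigma star point-spread sigma in pixels (default 1.2).
#' @return a \linkS4class{FixturePair}; star positions and peaks are in
#'   \code{meta$stars}.
#' @export
synthStarfieldPair <- function(seed, size = 256L, nStars = 80L,
                               dynRange = 1000, transform = similarityTransform(),
                               noiseSigma = 0, psfSigma = 1.2) {
  if (nStars < 10L) stop("nStars must be >= 10", call. = FALSE)
  minSep <- 6 * psfSigma
  peakMax <- 255 * 0.9
  floorSigma <- peakMax / dynRange / 20
  gen <- withSeed(seed, {
    pos <- matrix(NA_real_, 0, 2)
    guard <- 0L
    while (nrow(pos) < nStars && guard < 100000L) {
      guard <- guard + 1L
      p <- stats::runif(2, 8, size - 9)
      if (!nrow(pos) || min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)) > minSep)
        pos <- rbind(pos, p)
    }
    peaks <- peakMax * dynRange^(-stats::runif(nStars))
    bg <- abs(matrix(stats::rnorm(size * size, 0, floorSigma), size, size))
    list(pos = pos, peaks = peaks, bg = bg)
  })
  renderStars <- function(bg, pos, peaks) {
    P <- bg
    r <- ceiling(4 * psfSigma)
    for (i in seq_len(nrow(pos))) {
      x <- pos[i, 1]; y <- pos[i, 2]
      cx <- round(x); cy <- round(y)
      if (cx < -r || cx > size - 1L + r || cy < -r || cy > size - 1L + r)
        next
      xs <- max(0, cx - r):min(size - 1L, cx + r)
      ys <- max(0, cy - r):min(size - 1L, cy + r)
      g <- peaks[i] *
        exp(-(outer((ys - y)^2, (xs - x)^2, "+")) / (2 * psfSigma^2))
      P[ys + 1L, xs + 1L] <- P[ys + 1L, xs + 1L] + g
    }
    P
  }
  imgA <- clampGrayImage(renderStars(gen$bg, gen$pos, gen$peaks))
  posB <- applyTransform(transform, gen$pos)
  imgB <- withSeed(seed + 2000003L, {
    bgB <- abs(matrix(stats::rnorm(size * size, 0, floorSigma), size, size))
    clampGrayImage(renderStars(bgB, posB, gen$peaks) +
                   abs(stats::rnorm(size * size, 0, noiseSigma)))
  })
  new("FixturePair", imageA = imgA, imageB = imgB, truth = transform,
      meta = list(scenario = "starfield", seed = seed, size = size,
                  nStars = nStars, dynRange = dynRange,
                  noiseSigma = noiseSigma, psfSigma = psfSigma,
                  stars = cbind(gen$pos, peak = gen$peaks)))
}

#' Labelled synthetic point correspondences
#'
#' \code{n} source points drawn uniformly in a box; inlier destinations are
#' the ground-truth transform of the source plus isotropic Gaussian noise;
#' \code{round(n * outlierFrac)} outliers (the last rows, convenient for
#' quality-ordered consensus tests) get uniform random destinations over
#' the mapped region.
#'
#' @param seed integer seed.
#' @param n number of correspondences.
#' @param transform ground-truth \linkS4class{SimilarityTransform}.
#' @param outlierFrac fraction of outliers in \eqn{[0, 1)} (default 0).
#' @param noiseSigma per-axis Gaussian noise on inlier destinations
#'   (default 0).
#' @param boxSize side of the source sampling box (default 200).
#' @return list with \code{src}, \code{dst} (n x 2 matrices),
#'   \code{inlier} (logical labels) and \code{truth}.
#' @export
synthCorrespondences <- function(seed, n, transform = similarityTransform(),
                                 outlierFrac = 0, noiseSigma = 0,
                                 boxSize = 200) {
  if (outlierFrac < 0 || outlierFrac >= 1)
    stop("outlierFrac must lie in [0, 1)", call. = FALSE)
  nOut <- round(n * outlierFrac)
  withSeed(seed, {
    src <- cbind(stats::runif(n, 0, boxSize), stats::runif(n, 0, boxSize))
    dst <- applyTransform(transform, src) +
      matrix(stats::rnorm(2 * n, 0, noiseSigma), n, 2)
    inlier <- rep(TRUE, n)
    if (nOut > 0) {
      out <- seq.int(n - nOut + 1L, n)
      inlier[out] <- FALSE
      rng <- apply(applyTransform(transform,
                                  cbind(c(0, boxSize, 0, boxSize),
                                        c(0, 0, boxSize, boxSize))), 2, range)
      dst[out, 1] <- stats::runif(nOut, rng[1, 1], rng[2, 1])
      dst[out, 2] <- stats::runif(nOut, rng[1, 2], rng[2, 2])
    }
    list(src = src, dst = dst, inlier = inlier, truth = transform)
  })
}

#' @rdname FixturePair-class
#' @param x a \linkS4class{FixturePair}.
#' @export
fixtureImages <- function(x) list(A = x@imageA, B = x@imageB)

#' @rdname FixturePair-class
#' @export
fixtureTruth <- function(x) x@truth

setMethod("show", "FixturePair", function(object) {
  cat(sprintf("FixturePair [%s]: %d x %d images, seed %s\n",
              object@meta$scenario, nrow(object@imageA), ncol(object@imageA),
              format(object@meta$seed)))
  show(object@truth)
})

#' Write a fixture pair to disk
#'
#' Writes \code{imageA.png}, \code{imageB.png} and \code{truth.json}
#' (plus metadata) into a directory.
#'
#' @param pair a \linkS4class{FixturePair}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFixturePair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGrayImage(pair@imageA, file.path(dir, "imageA.png"))
  writeGrayImage(pair@imageB, file.path(dir, "imageB.png"))
  writeTransformJSON(pair@truth, file.path(dir, "truth.json"))
  jsonlite::write_json(pair@meta[setdiff(names(pair@meta), "stars")],
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
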