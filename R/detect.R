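# FAST-9 detection, Harris response selection, intensity-centroid orientation.
# Coordinates are 0-based, x = column, y = row, origin top-left.

# the 16 Bresenham circle offsets (radius 3) in circular order, (dx, dy)
.FAST_CIRCLE <- cbind(
  dx = c(0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L, -3L, -3L, -2L, -1L),
  dy = c(-3L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L))

#' FAST-9 corner detection
#'
#' Segment test on the 16-pixel Bresenham circle of radius 3: a pixel is a
#' corner candidate when at least 9 contiguous circle neighbours are all
#' brighter than the centre by more than \code{xi}, or all darker by more
#' than \code{xi}. The returned response is the whole-circle sum of absolute
#' centre differences, usable for thresholding and non-maximum suppression.
#'
#' @param image a \linkS4class{GrayImage}, at least 32 x 32.
#' @param xi intensity threshold, \code{0 < xi < 255} (default 40).
#' @return keypoint table (columns \code{x, y, level, scale, response,
#'   orientation}) with positions only; \code{orientation} is NA until
#'   [computeOrientation()] fills it.
#' @examples
#' img <- GrayImage(matrix(0, 64, 64))
#' img[21:40, 21:40] <- 255
#' head(fast9Detect(img))
#' @seealso [harrisSelect()], [detectKeypoints()]
#' @export
fast9Detect <- function(image, xi = 40) {
  stopifnot(is(image, "GrayImage"))
  .checkImageSize(image)
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0 || xi >= 255)
    stop("xi must satisfy 0 < xi < 255", call. = FALSE)
  P <- image@.Data
  h <- nrow(P); w <- ncol(P)
  rows <- 4:(h - 3L); cols <- 4:(w - 3L)
  nr <- length(rows); nc <- length(cols); np <- nr * nc
  C <- P[rows, cols]
  bright <- matrix(FALSE, np, 16L)
  dark <- matrix(FALSE, np, 16L)
  resp <- numeric(np)
  for (k in 1:16) {
    d <- P[rows + .FAST_CIRCLE[k, "dy"], cols + .FAST_CIRCLE[k, "dx"]] - C
    bright[, k] <- d > xi
    dark[, k] <- d < -xi
    resp <- resp + abs(d)
  }
  run9 <- function(B) {
    ext <- cbind(B, B[, 1:8, drop = FALSE])
    ok <- logical(np)
    for (s in 1:16)
      ok <- ok | (rowSums(ext[, s:(s + 8L), drop = FALSE]) == 9L)
    ok
  }
  corner <- run9(bright) | run9(dark)
  if (!any(corner)) return(asKeypointTable(numeric(0), numeric(0)))
  idx <- which(corner)
  r <- rows[((idx - 1L) %% nr) + 1L]
  cc <- cols[((idx - 1L) %/% nr) + 1L]
  kp <- asKeypointTable(x = cc - 1L, y = r - 1L, response = resp[idx])
  kp[order(kp$y, kp$x), , drop = FALSE]
}

#' 3 x 3 non-maximum suppression on the FAST response
#'
#' Keeps a candidate only when its response is at least that of every
#' 8-neighbour candidate, removing duplicate detections of one corner.
#'
#' @param image the \linkS4class{GrayImage} the candidates came from.
#' @param candidates keypoint table from [fast9Detect()].
#' @return the suppressed keypoint table.
#' @export
fastNonMaxSuppress <- function(image, candidates) {
  if (!nrow(candidates)) return(candidates)
  h <- nrow(image); w <- ncol(image)
  R <- matrix(-Inf, h, w)
  ri <- candidates$y + 1L; ci <- candidates$x + 1L
  R[cbind(ri, ci)] <- candidates$response
  keep <- rep(TRUE, nrow(candidates))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    keep <- keep & candidates$response >= R[cbind(ri + dy, ci + dx)]
  }
  candidates[keep, , drop = FALSE]
}

# separable convolution helpers for the Harris maps (zero padding; scores
# are only read at candidate sites well inside the border)
.convRows <- function(m, k) {
  half <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {
    s <- i - 1L - half
    src <- seq_len(nrow(m)) + s
    ok <- src >= 1L & src <= nrow(m)
    out[ok, ] <- out[ok, ] + k[i] * m[src[ok], , drop = FALSE]
  }
  out
}

.convCols <- function(m, k) t(.convRows(t(m), k))

.gaussKernel1d <- function(size, sigma) {
  half <- (size - 1L) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Harris response selection
#'
#' Scores candidates with the Harris corner response
#' \eqn{\det(M) - k\,\mathrm{tr}(M)^2} of the Gaussian-weighted (7 x 7,
#' sigma 1.5) gradient structure tensor built from Sobel derivatives, then
#' keeps the \code{nKeep} strongest. Candidates closer than 5 px to the
#' border (where the tensor window is incomplete) are dropped first.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param candidates keypoint table (e.g. from [fast9Detect()]).
#' @param nKeep number of keypoints to keep (default 500).
#' @param k Harris sensitivity constant (default 0.04).
#' @return keypoint table sorted by response descending (ties broken by
#'   \code{(y, x)}), truncated to \code{nKeep}.
#' @export
harrisSelect <- function(image, candidates, nKeep = 500, k = 0.04) {
  if (!is.numeric(nKeep) || length(nKeep) != 1L || nKeep < 0)
    stop("nKeep must be a non-negative count", call. = FALSE)
  nKeep <- as.integer(nKeep)
  if (nKeep == 0L || !nrow(candidates))
    return(candidates[integer(0), , drop = FALSE])
  P <- image@.Data
  h <- nrow(P); w <- ncol(P)
  inb <- candidates$x >= 5 & candidates$x <= w - 6 &
         candidates$y >= 5 & candidates$y <= h - 6
  candidates <- candidates[inb, , drop = FALSE]
  if (!nrow(candidates)) return(candidates)
  # Sobel derivatives (separable: smooth [1 2 1], diff [-1 0 1])
  Ix <- .convCols(.convRows(P, c(1, 2, 1)), c(-1, 0, 1)) / 8
  Iy <- .convCols(.convRows(P, c(-1, 0, 1)), c(1, 2, 1)) / 8
  g <- .gaussKernel1d(7L, 1.5)
  A <- .convCols(.convRows(Ix * Ix, g), g)
  B <- .convCols(.convRows(Iy * Iy, g), g)
  Cc <- .convCols(.convRows(Ix * Iy, g), g)
  idx <- cbind(candidates$y + 1L, candidates$x + 1L)
  score <- (A[idx] * B[idx] - Cc[idx]^2) - k * (A[idx] + B[idx])^2
  candidates$response <- score
  ord <- order(-score, candidates$y, candidates$x)
  candidates[ord[seq_len(min(nKeep, length(ord)))], , drop = FALSE]
}

#' Intensity-centroid orientation
#'
#' The dominant orientation of each keypoint is the angle of the intensity
#' centroid of its circular patch: \eqn{\alpha = \mathrm{atan2}(M_{01},
#' M_{10})} with moments \eqn{M_{pq} = \sum x^p y^q I(x, y)} over
#' keypoint-relative offsets (x right, y down). A point-symmetric patch
#' (both moments zero) gets \eqn{\alpha = 0} by convention.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param keypoints keypoint table; coordinates in this image's frame.
#' @param radius circular patch radius in pixels (default 15).
#' @return the keypoint table with \code{orientation} filled, in
#'   \eqn{(-\pi, \pi]}.
#' @export
computeOrientation <- function(image, keypoints, radius = 15) {
  if (!nrow(keypoints)) return(keypoints)
  P <- image@.Data
  h <- nrow(P); w <- ncol(P)
  if (any(keypoints$x < radius | keypoints$x > w - 1 - radius |
          keypoints$y < radius | keypoints$y > h - 1 - radius))
    stop("orientation patch exceeds image bounds", call. = FALSE)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  ri <- outer(offs$dy, keypoints$y + 1L, "+")
  ci <- outer(offs$dx, keypoints$x + 1L, "+")
  patch <- matrix(P[cbind(as.vector(ri), as.vector(ci))], nrow(offs))
  m10 <- colSums(offs$dx * patch)
  m01 <- colSums(offs$dy * patch)
  keypoints$orientation <- atan2(m01, m10)
  keypoints
}

#' Detect oriented keypoints in one image
#'
#' Convenience wrapper running the full single-level detection chain:
#' FAST-9 segment test, border filtering, 3 x 3 non-maximum suppression,
#' Harris selection, intensity-centroid orientation.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param xi FAST intensity threshold (default 40).
#' @param nKeep number of keypoints kept by Harris selection (default 500).
#' @param border minimum distance from the border (default 16 px, enough
#'   for the steered 31 x 31 descriptor patch with 5 x 5 sub-windows).
#' @param orientationRadius patch radius for [computeOrientation()].
#' @return oriented keypoint table.
#' @export
detectKeypoints <- function(image, xi = 40, nKeep = 500, border = 16L,
                            orientationRadius = 15) {
  kp <- fast9Detect(image, xi = xi)
  h <- nrow(image); w <- ncol(image)
  kp <- kp[kp$x >= border & kp$x <= w - 1L - border &
           kp$y >= border & kp$y <= h - 1L - border, , drop = FALSE]
  kp <- fastNonMaxSuppress(image, kp)
  kp <- harrisSelect(image, kp, nKeep = nKeep)
  computeOrientation(image, kp, radius = orientationRadius)
}
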