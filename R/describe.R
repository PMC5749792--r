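# Steered 256-bit sub-window BRIEF descriptors.

#' Generate a random descriptor sampling pattern
#'
#' Draws point pairs from an isotropic Gaussian (sigma = patchHalf / 2),
#' rounded to integer offsets and rejection-clipped to the disk of radius
#' \code{patchHalf - subwindow %/% 2}, so that every steered sample's
#' sub-window stays inside the patch. Deterministic for a fixed
#' \code{(seed, patchHalf)}; the caller's RNG state is untouched.
#'
#' @param seed integer RNG seed (default 42, the package-wide default
#'   pattern).
#' @param patchHalf half-size of the square descriptor patch (>= 8,
#'   default 15 for a 31 x 31 patch).
#' @param k number of pairs (default 256).
#' @param subwindow side length of the box-sum sub-window (default 5).
#' @return a \linkS4class{SamplingPattern}.
#' @export
generatePattern <- function(seed = 42, patchHalf = 15L, k = 256L,
                            subwindow = 5L) {
  if (patchHalf < 8) stop("patchHalf must be >= 8", call. = FALSE)
  rmax <- patchHalf - subwindow %/% 2L
  withSeed(seed, {
    draw <- function(n) {
      out <- matrix(NA_integer_, 0, 2)
      while (nrow(out) < n) {
        m <- matrix(as.integer(round(rnorm(2 * n, 0, patchHalf / 2))),
                    ncol = 2)
        m <- m[m[, 1]^2 + m[, 2]^2 <= rmax^2, , drop = FALSE]
        out <- rbind(out, m)
      }
      out[seq_len(n), , drop = FALSE]
    }
    pairs <- cbind(draw(k), draw(k))
  })
  colnames(pairs) <- c("mx", "my", "nx", "ny")
  new("SamplingPattern", pairs = pairs, patchHalf = as.integer(patchHalf))
}

# bit matrix (patches x tests) of un-steered sub-window comparisons at the
# centre of each training patch
.patchBits <- function(tests, patches, subwindow = 5L) {
  vapply(patches, function(p) {
    P <- if (is(p, "GrayImage")) p@.Data else as.matrix(p)
    II <- .integralImage(P)
    cy <- (nrow(P) - 1) %/% 2L; cx <- (ncol(P) - 1) %/% 2L
    sm <- .boxSums(II, cy + 1L + tests[, "my"], cx + 1L + tests[, "mx"],
                   subwindow, nrow(P), ncol(P))
    sn <- .boxSums(II, cy + 1L + tests[, "ny"], cx + 1L + tests[, "nx"],
                   subwindow, nrow(P), ncol(P))
    as.integer(sm < sn)
  }, integer(nrow(tests)))
}

#' Greedy selection of de-correlated binary tests
#'
#' Reproduces the de-correlation step of learned binary descriptors: each
#' candidate test is evaluated on a training-patch corpus; candidates are
#' ranked by how close their mean bit is to 0.5 (most discriminative
#' first) and accepted greedily when the absolute Pearson correlation of
#' their bit column with every already-accepted column stays below
#' \code{corThreshold}. If the threshold is exhausted before \code{k} tests
#' are found it is relaxed in steps of 0.05.
#'
#' @param candidateTests integer matrix with columns \code{mx, my, nx, ny},
#'   one candidate test per row (at least \code{k} rows).
#' @param trainingPatches list of (at least 50) square GrayImage patches.
#' @param k number of tests to select (default 256).
#' @param corThreshold initial absolute-correlation bound (default 0.2).
#' @param patchHalf patch half-size recorded on the result (default 15).
#' @param subwindow box-sum sub-window side (default 5).
#' @return a \linkS4class{SamplingPattern} of the selected tests.
#' @export
learnPatternGreedy <- function(candidateTests, trainingPatches, k = 256L,
                               corThreshold = 0.2, patchHalf = 15L,
                               subwindow = 5L) {
  candidateTests <- as.matrix(candidateTests)
  colnames(candidateTests) <- c("mx", "my", "nx", "ny")
  if (nrow(candidateTests) < k)
    stop("need at least k = ", k, " candidate tests", call. = FALSE)
  bits <- t(.patchBits(candidateTests, trainingPatches, subwindow))
  sel <- greedyDecorrelate(bits, k, corThreshold)
  new("SamplingPattern",
      pairs = candidateTests[sel, , drop = FALSE],
      patchHalf = as.integer(patchHalf))
}

#' @describeIn learnPatternGreedy the greedy core on a precomputed bit
#'   matrix (patches x tests); returns the selected column indices. Exposed
#'   so the selection rule can be checked independently of patch handling.
#' @param bits 0/1 matrix, one column per candidate test.
#' @export
greedyDecorrelate <- function(bits, k, corThreshold = 0.2) {
  n <- ncol(bits)
  if (n < k) stop("need at least k candidate columns", call. = FALSE)
  ord <- order(abs(colMeans(bits) - 0.5), seq_len(n))
  sel <- integer(0)
  thr <- corThreshold
  remaining <- ord
  repeat {
    nxt <- integer(0)
    for (j in remaining) {
      if (length(sel) >= k) break
      cors <- if (length(sel)) {
        vapply(sel, function(s) {
          v <- suppressWarnings(stats::cor(bits[, j], bits[, s]))
          if (is.na(v)) 1 else abs(v)   # constant columns: uninformative
        }, numeric(1))
      } else numeric(0)
      if (!length(cors) || max(cors) < thr) sel <- c(sel, j)
      else nxt <- c(nxt, j)
    }
    if (length(sel) >= k || !length(nxt)) break
    if (thr > 1.01) { sel <- c(sel, nxt[seq_len(k - length(sel))]); break }
    thr <- thr + 0.05
    remaining <- nxt
  }
  sel[seq_len(min(k, length(sel)))]
}

#' Steer a sampling pattern by an angle
#'
#' Applies the pattern rotation \eqn{S' = [[\cos\alpha, \sin\alpha],
#' [-\sin\alpha, \cos\alpha]] \cdot S}, i.e. \eqn{(x, y) \mapsto
#' (x\cos\alpha + y\sin\alpha,\; -x\sin\alpha + y\cos\alpha)}, rounding to
#' the nearest integer offset. Note this matrix rotates the pattern
#' clockwise for positive \code{alpha} in y-down pixel coordinates; the
#' descriptor ([describeKeypoints()]) steers by the inverse angle so that
#' the sampled constellation follows the keypoint orientation.
#'
#' @param pattern a \linkS4class{SamplingPattern}.
#' @param alpha angle in radians.
#' @return the steered \linkS4class{SamplingPattern}.
#' @export
steerPattern <- function(pattern, alpha) {
  p <- pattern@pairs
  ca <- cos(alpha); sa <- sin(alpha)
  rot <- function(x, y) cbind(round(x * ca + y * sa), round(-x * sa + y * ca))
  m <- rot(p[, "mx"], p[, "my"])
  n <- rot(p[, "nx"], p[, "ny"])
  out <- cbind(m, n)
  storage.mode(out) <- "integer"
  colnames(out) <- c("mx", "my", "nx", "ny")
  new("SamplingPattern", pairs = out, patchHalf = pattern@patchHalf)
}

# integral image: II is (h+1) x (w+1) with II[i+1, j+1] = sum P[1:i, 1:j]
.integralImage <- function(P) {
  A <- apply(P, 2L, cumsum)
  A <- t(apply(A, 1L, cumsum))
  rbind(0, cbind(0, A))
}

# box sums of the (side x side) windows centred at 1-based (r, c);
# errors when a window leaves the image
.boxSums <- function(II, r, c, side, h, w) {
  half <- side %/% 2L
  if (any(r - half < 1L) || any(r + half > h) ||
      any(c - half < 1L) || any(c + half > w))
    stop("descriptor sample window out of image bounds", call. = FALSE)
  r0 <- as.vector(r) - half; r1 <- as.vector(r) + half + 1L
  c0 <- as.vector(c) - half; c1 <- as.vector(c) + half + 1L
  nr <- nrow(II)
  II[(c1 - 1L) * nr + r1] - II[(c0 - 1L) * nr + r1] -
    II[(c1 - 1L) * nr + r0] + II[(c0 - 1L) * nr + r0]
}

#' Compute steered sub-window BRIEF descriptors
#'
#' For each keypoint the sampling pattern is steered by the keypoint
#' orientation; each binary test compares the box sums of the
#' \code{subwindow x subwindow} neighbourhoods (integral-image
#' implementation) centred at the two steered sample points, with bit = 1
#' iff the first sum is strictly smaller (ties give 0). By default steered
#' patterns are cached at \code{nAngles} discrete orientations (12 degrees
#' per bin for 30) for determinism and speed; \code{exact = TRUE} steers
#' per keypoint instead.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param keypoints oriented keypoint table in this image's frame.
#' @param pattern a \linkS4class{SamplingPattern}
#'   (default \code{generatePattern(42)}).
#' @param subwindow box side length in pixels (default 5).
#' @param nAngles number of quantized steering angles (default 30).
#' @param exact steer per keypoint angle instead of quantizing.
#' @return a \linkS4class{BinaryDescriptors} with one column per keypoint.
#' @export
describeKeypoints <- function(image, keypoints, pattern = generatePattern(),
                              subwindow = 5L, nAngles = 30L, exact = FALSE) {
  P <- image@.Data
  h <- nrow(P); w <- ncol(P)
  nk <- nrow(keypoints)
  kbits <- matrix(0L, nrow(pattern@pairs), nk)
  if (!nk) return(new("BinaryDescriptors", bits = kbits))
  II <- .integralImage(P)
  alpha <- keypoints$orientation
  alpha[is.na(alpha)] <- 0
  # steer by -alpha: steerPattern applies the printed matrix R(-a), so the
  # sample constellation is rotated by +alpha, following the patch content
  if (exact) {
    bin <- seq_len(nk); binAngle <- alpha
  } else {
    step <- 2 * pi / nAngles
    bin <- (round(alpha / step) %% nAngles) + 1L
    binAngle <- (seq_len(nAngles) - 1L) * step
  }
  for (b in unique(bin)) {
    sp <- steerPattern(pattern, -binAngle[b])@pairs
    ki <- which(bin == b)
    rm_ <- outer(sp[, "my"], keypoints$y[ki] + 1L, "+")
    cm_ <- outer(sp[, "mx"], keypoints$x[ki] + 1L, "+")
    rn_ <- outer(sp[, "ny"], keypoints$y[ki] + 1L, "+")
    cn_ <- outer(sp[, "nx"], keypoints$x[ki] + 1L, "+")
    sm <- .boxSums(II, rm_, cm_, subwindow, h, w)
    sn <- .boxSums(II, rn_, cn_, subwindow, h, w)
    kbits[, ki] <- matrix(as.integer(sm < sn), nrow(sp))
  }
  new("BinaryDescriptors", bits = kbits)
}

#' @rdname BinaryDescriptors-class
#' @param object,x a \linkS4class{BinaryDescriptors}.
#' @export
descriptorBits <- function(x) x@bits

setMethod("show", "BinaryDescriptors", function(object) {
  cat(sprintf("BinaryDescriptors: %d descriptors of %d bits\n",
              ncol(object@bits), nrow(object@bits)))
})

setMethod("show", "SamplingPattern", function(object) {
  cat(sprintf("SamplingPattern: %d point pairs, patch half-size %d\n",
              nrow(object@pairs), object@patchHalf))
})
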