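# Least-squares similarity/rigid transform fit and progressive sample
# consensus (PROSAC) screening, with a uniform RANSAC baseline.

#' Least-squares similarity transform between point sets
#'
#' Closed-form Procrustes estimate of rotation, translation and optional
#' isotropic scale minimizing \eqn{\sum \|M p - p'\|^2} over corresponding
#' pairs: the rotation angle comes from the centred cross-covariance,
#' \eqn{\alpha = \mathrm{atan2}(\sum(x y' - y x'), \sum(x x' + y y'))},
#' the scale from its norm, and the translation from the centroids. The
#' estimate is always a proper rotation; a reflective correspondence gets
#' the best proper rotation with (necessarily) large residuals, which
#' [transformResiduals()] exposes.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 2,
#'   source not all coincident.
#' @param allowScale estimate isotropic scale (default TRUE); FALSE fixes
#'   s = 1 (the rigid rotation-translation form).
#' @return a \linkS4class{SimilarityTransform} mapping src to dst.
#' @export
estimateTransform <- function(src, dst, allowScale = TRUE) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) stop("point counts differ", call. = FALSE)
  if (nrow(src) < 2L) stop("need at least 2 point pairs", call. = FALSE)
  cs <- colMeans(src); cd <- colMeans(dst)
  ps <- sweep(src, 2, cs); pd <- sweep(dst, 2, cd)
  den <- sum(ps^2)
  if (den < 1e-12) stop("degenerate input: source points coincide",
                        call. = FALSE)
  A <- sum(ps[, 1] * pd[, 1] + ps[, 2] * pd[, 2])
  B <- sum(ps[, 1] * pd[, 2] - ps[, 2] * pd[, 1])
  alpha <- atan2(B, A)
  s <- if (allowScale) sqrt(A^2 + B^2) / den else 1
  if (s <= 0) s <- 1e-12
  ca <- cos(alpha); sa <- sin(alpha)
  t0 <- cd - s * c(ca * cs[1] - sa * cs[2], sa * cs[1] + ca * cs[2])
  similarityTransform(alpha, t0[1], t0[2], s)
}

#' Squared residuals of correspondences under a transform
#'
#' @param transform a \linkS4class{SimilarityTransform}.
#' @param src,dst corresponding point matrices.
#' @return numeric vector of squared residuals \eqn{\|M p - p'\|^2}.
#' @export
transformResiduals <- function(transform, src, dst) {
  r <- applyTransform(transform, src) - as.matrix(dst)
  rowSums(r^2)
}

.consensusLoop <- function(srcPts, dstPts, order, progressive, tauIn,
                           tauRatio, tauGrow, maxIter, patience, eta0,
                           allowScale) {
  n <- nrow(srcPts)
  bestCnt <- 0L; bestIn <- rep(FALSE, n); bestErr <- Inf
  history <- integer(0)
  termination <- "max_iter"
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    if (progressive) {
      eta <- min(eta0 + it - 1L, n)
      pick <- order[c(sample.int(eta - 1L, 3L), eta)]
    } else {
      pick <- sample.int(n, 4L)
    }
    fit <- tryCatch(
      estimateTransform(srcPts[pick, , drop = FALSE],
                        dstPts[pick, , drop = FALSE], allowScale),
      error = function(e) NULL)
    if (!is.null(fit)) {
      res <- transformResiduals(fit, srcPts, dstPts)
      inl <- res <= tauIn
      cnt <- sum(inl)
      err <- sum(res[inl])
      if (cnt > bestCnt || (cnt == bestCnt && err < bestErr)) {
        bestCnt <- cnt; bestIn <- inl; bestErr <- err
      }
    }
    history[it] <- bestCnt
    if (bestCnt / n > tauRatio) { termination <- "ratio"; break }
    if (it > patience && bestCnt >= 4L &&
        (history[it] - history[it - patience]) / patience < tauGrow) {
      termination <- "growth"; break
    }
  }
  list(inliers = bestIn, nIterations = it, termination = termination,
       history = history)
}

.refitConsensus <- function(loop, srcPts, dstPts, tauIn, allowScale) {
  inl <- loop$inliers
  transform <- NULL
  if (sum(inl) >= 2L) {
    for (pass in 1:3) {
      transform <- estimateTransform(srcPts[inl, , drop = FALSE],
                                     dstPts[inl, , drop = FALSE], allowScale)
      newIn <- transformResiduals(transform, srcPts, dstPts) <= tauIn
      if (identical(newIn, inl) || sum(newIn) < 2L) break
      inl <- newIn
    }
    # final flags must satisfy the bound under the final transform
    inl <- transformResiduals(transform, srcPts, dstPts) <= tauIn
  }
  new("ConsensusResult", transform = transform, inliers = inl,
      nIterations = as.integer(loop$nIterations),
      termination = loop$termination,
      history = as.integer(loop$history), tauIn = tauIn)
}

#' Progressive sample consensus (PROSAC) match screening
#'
#' Matches are sorted by quality descending (geometric-cost
#' distinctiveness when available, otherwise negative Hamming distance).
#' Each iteration draws a minimal set biased to the current top-\eqn{\eta}
#' prefix — three pairs uniformly from the prefix plus the \eqn{\eta}-th
#' ranked pair — with \eqn{\eta} starting at \code{eta0} (default 4) and
#' growing by one per iteration; a similarity transform is fitted and
#' matches within the squared-residual bound \code{tauIn} are counted as
#' inliers. Sampling stops when the best inlier fraction exceeds
#' \code{tauRatio}, when the best inlier count grows slower than
#' \code{tauGrow} per iteration over a \code{patience} window, or at
#' \code{maxIter}. The final transform is re-fitted on the consensus set.
#'
#' Randomness is drawn from R's RNG: pass \code{seed} (recommended) for an
#' exactly reproducible result, or seed the session RNG yourself.
#'
#' @param matches match table; its \code{quality} column (falling back to
#'   \code{-hamming}, then input order) defines the progressive order.
#' @param srcPts,dstPts n x 2 coordinate matrices aligned with
#'   \code{matches} rows.
#' @param tauIn inlier bound on the squared residual, pixels^2 (default 9,
#'   a 3 px residual).
#' @param tauRatio inlier-fraction termination threshold (default 0.5).
#' @param tauGrow minimum inlier growth rate per iteration (default 0.1,
#'   i.e. one new inlier per 10 iterations).
#' @param maxIter iteration cap (default 1000).
#' @param patience growth-window length in iterations (default 10).
#' @param eta0 initial sample-prefix size (default 4).
#' @param allowScale estimate scale in the fits (default TRUE).
#' @param seed optional integer seed for reproducible sampling.
#' @return a \linkS4class{ConsensusResult}.
#' @export
prosacFilter <- function(matches, srcPts, dstPts, tauIn = 9,
                         tauRatio = 0.5, tauGrow = 0.1, maxIter = 1000L,
                         patience = 10L, eta0 = 4L, allowScale = TRUE,
                         seed = NULL) {
  srcPts <- as.matrix(srcPts); dstPts <- as.matrix(dstPts)
  n <- nrow(matches)
  if (n < eta0) stop("need at least eta0 = ", eta0, " matches",
                     call. = FALSE)
  q <- matches$quality
  if (all(is.na(q))) q <- -matches$hamming
  q[is.na(q)] <- -Inf
  ord <- order(-q, seq_len(n))
  run <- function() .consensusLoop(srcPts, dstPts, ord, TRUE, tauIn,
                                   tauRatio, tauGrow, maxIter, patience,
                                   eta0, allowScale)
  loop <- if (is.null(seed)) run() else withSeed(seed, run())
  .refitConsensus(loop, srcPts, dstPts, tauIn, allowScale)
}

#' Uniform-sampling RANSAC baseline
#'
#' Classic RANSAC with the same transform model and inlier rule as
#' [prosacFilter()] but uniform minimal samples of 4 and the standard
#' adaptive iteration bound (confidence 0.99), for A/B comparison.
#'
#' @inheritParams prosacFilter
#' @param confidence target probability of one outlier-free sample
#'   (default 0.99).
#' @return a \linkS4class{ConsensusResult}.
#' @export
ransacBaseline <- function(matches, srcPts, dstPts, tauIn = 9,
                           maxIter = 1000L, allowScale = TRUE,
                           confidence = 0.99, seed = NULL) {
  srcPts <- as.matrix(srcPts); dstPts <- as.matrix(dstPts)
  n <- nrow(matches)
  if (n < 4L) stop("need at least 4 matches", call. = FALSE)
  run <- function() {
    bestCnt <- 0L; bestIn <- rep(FALSE, n); bestErr <- Inf
    history <- integer(0)
    needed <- maxIter
    it <- 0L
    while (it < min(needed, maxIter)) {
      it <- it + 1L
      pick <- sample.int(n, 4L)
      fit <- tryCatch(
        estimateTransform(srcPts[pick, , drop = FALSE],
                          dstPts[pick, , drop = FALSE], allowScale),
        error = function(e) NULL)
      if (!is.null(fit)) {
        res <- transformResiduals(fit, srcPts, dstPts)
        inl <- res <= tauIn
        cnt <- sum(inl)
        err <- sum(res[inl])
        if (cnt > bestCnt || (cnt == bestCnt && err < bestErr)) {
          bestCnt <- cnt; bestIn <- inl; bestErr <- err
          w <- max(cnt / n, 1e-6)
          needed <- if (w >= 1) it
            else ceiling(log(1 - confidence) / log(1 - w^4))
        }
      }
      history[it] <- bestCnt
    }
    list(inliers = bestIn, nIterations = it,
         termination = if (it < maxIter) "ratio" else "max_iter",
         history = history)
  }
  loop <- if (is.null(seed)) run() else withSeed(seed, run())
  .refitConsensus(loop, srcPts, dstPts, tauIn, allowScale)
}

#' @rdname ConsensusResult-class
#' @param x a \linkS4class{ConsensusResult}.
#' @export
inlierFlags <- function(x) x@inliers

#' @rdname ConsensusResult-class
#' @export
finalTransform <- function(x) x@transform

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: %d/%d inliers, %d iteration(s), terminated on '%s'\n",
    sum(object@inliers), length(object@inliers), object@nIterations,
    object@termination))
  if (!is.null(object@transform)) show(object@transform)
})
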