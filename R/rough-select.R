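# Rough selection: Hamming distance, mean-centred distance window,
# bidirectional KNN ratio test.

.bitsOf <- function(x) {
  if (is(x, "BinaryDescriptors")) x@bits
  else if (is.numeric(x) || is.logical(x)) as.matrix(as.integer(x))
  else stop("expected a BinaryDescriptors or a bit vector", call. = FALSE)
}

#' Hamming distance between two 256-bit descriptors
#'
#' Popcount of the XOR of the two bit strings.
#'
#' @param a,b 256-bit descriptors: single-column
#'   \linkS4class{BinaryDescriptors} or 0/1 vectors of length 256.
#' @return integer distance in \eqn{[0, 256]}.
#' @examples
#' hammingDistance(rep(0, 256), rep(1, 256))  # 256
#' @export
hammingDistance <- function(a, b) {
  va <- .bitsOf(a); vb <- .bitsOf(b)
  if (ncol(va) != 1L || ncol(vb) != 1L)
    stop("hammingDistance compares exactly two descriptors", call. = FALSE)
  if (nrow(va) != nrow(vb))
    stop("descriptor lengths differ", call. = FALSE)
  sum(va[, 1] != vb[, 1])
}

#' Full Hamming distance matrix between two descriptor sets
#'
#' Uses the identity \eqn{D = |a| + |b| - 2 a \cdot b} on the 0/1 bit
#' columns, so the whole matrix is one cross-product.
#'
#' @param descA,descB \linkS4class{BinaryDescriptors}.
#' @return integer matrix, rows indexing \code{descA} columns.
#' @export
hammingMatrix <- function(descA, descB) {
  A <- .bitsOf(descA); B <- .bitsOf(descB)
  if (nrow(A) != nrow(B)) stop("descriptor lengths differ", call. = FALSE)
  D <- outer(colSums(A), colSums(B), "+") - 2 * crossprod(A, B)
  storage.mode(D) <- "integer"
  D
}

#' Mean-centred Hamming distance window filter
#'
#' Retains matches whose Hamming distance lies in
#' \eqn{[\bar D - \epsilon_1, \bar D + \epsilon_2]} (inclusive) where
#' \eqn{\bar D} is the mean distance, \eqn{\epsilon_1 = (\bar D -
#' D_{min})/2} and \eqn{\epsilon_2 = (D_{max} - \bar D)/2} — the midpoint
#' ("medium value") between each extreme and the mean. When all distances
#' are equal the window collapses to a point and every match is retained.
#'
#' @param matches match table with a \code{hamming} column.
#' @return list with \code{matches} (retained rows, stage set to
#'   \code{"window"}) and \code{window} (a \linkS4class{DistanceWindow},
#'   NULL for empty input).
#' @examples
#' m <- asMatchTable(1:5, 1:5, hamming = c(10, 20, 30, 40, 50))
#' distanceWindowFilter(m)$matches$hamming  # 20 30 40
#' @export
distanceWindowFilter <- function(matches) {
  if (!nrow(matches)) return(list(matches = emptyMatches(), window = NULL))
  D <- matches$hamming
  dBar <- mean(D)
  eps1 <- (dBar - min(D)) / 2
  eps2 <- (max(D) - dBar) / 2
  keep <- D >= dBar - eps1 & D <= dBar + eps2
  out <- matches[keep, , drop = FALSE]
  if (nrow(out)) out$stage <- "window"
  list(matches = out,
       window = new("DistanceWindow", dBar = dBar, eps1 = eps1, eps2 = eps2))
}

#' @rdname DistanceWindow-class
#' @param x a \linkS4class{DistanceWindow}.
#' @export
windowBounds <- function(x) c(lo = x@dBar - x@eps1, hi = x@dBar + x@eps2)

setMethod("show", "DistanceWindow", function(object) {
  b <- windowBounds(object)
  cat(sprintf("DistanceWindow: mean %.2f, window [%.2f, %.2f]\n",
              object@dBar, b["lo"], b["hi"]))
})

#' Bidirectional KNN ratio matching
#'
#' For every descriptor of one set the nearest and second-nearest
#' descriptors of the other set are found by Hamming distance; the match is
#' kept when the optimal/sub-optimal ratio is below \code{t}. The test is
#' applied in both directions and only mutual nearest neighbours passing
#' both directions are returned, so the output is a partial one-to-one
#' matching. Ties for (second-)nearest break toward the lower index; a side
#' with a single descriptor has no competitor and its ratio is taken as 0;
#' a zero second-nearest distance (duplicate descriptors) gives ratio 1
#' (ambiguous, rejected for \code{t < 1}).
#'
#' @param descA,descB \linkS4class{BinaryDescriptors}.
#' @param t ratio threshold in \eqn{(0, 1]} (default 0.65).
#' @return match table with \code{hamming} filled and stage
#'   \code{"bidirectional"}.
#' @export
bidirectionalRatioMatch <- function(descA, descB, t = 0.65) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1)
    stop("t must lie in (0, 1]", call. = FALSE)
  D <- hammingMatrix(descA, descB)
  nA <- nrow(D); nB <- ncol(D)
  if (!nA || !nB) return(emptyMatches())
  top2 <- function(v) {
    o1 <- which.min(v)
    d1 <- v[o1]
    if (length(v) == 1L) return(c(o1, d1, NA))
    d2 <- min(v[-o1])
    c(o1, d1, d2)
  }
  fwd <- t(apply(D, 1L, top2))   # nearest in B for each a
  bwd <- t(apply(D, 2L, top2))   # nearest in A for each b
  ratio <- function(d1, d2) {
    r <- ifelse(is.na(d2), 0, ifelse(d2 == 0, 1, d1 / d2))
    r
  }
  passA <- ratio(fwd[, 2], fwd[, 3]) < t
  passB <- ratio(bwd[, 2], bwd[, 3]) < t
  i <- seq_len(nA)
  j <- fwd[, 1]
  mutual <- bwd[j, 1] == i
  keep <- passA & passB[j] & mutual
  asMatchTable(i[keep], j[keep], hamming = fwd[keep, 2],
               stage = "bidirectional")
}
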