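# SimilarityTransform construction, application, algebra, serialization.

#' Create a similarity transform
#'
#' @param alpha rotation angle in radians.
#' @param du,dv translation in pixels.
#' @param s isotropic scale (default 1, the rigid rotation-translation
#'   form).
#' @return a \linkS4class{SimilarityTransform}.
#' @examples
#' tf <- similarityTransform(pi / 6, 12, -7)
#' applyTransform(tf, cbind(0, 0))
#' @export
similarityTransform <- function(alpha = 0, du = 0, dv = 0, s = 1) {
  new("SimilarityTransform", alpha = as.numeric(alpha), du = as.numeric(du),
      dv = as.numeric(dv), s = as.numeric(s))
}

#' Rotation (with optional scale) about an arbitrary centre
#'
#' Convenience constructor for fixtures: rotate by \code{alpha} (and scale
#' by \code{s}) about \code{center}, then translate.
#'
#' @param center length-2 centre of rotation (x, y), 0-based pixels.
#' @param alpha rotation in radians.
#' @param s isotropic scale (default 1).
#' @param translation additional translation c(du, dv) (default none).
#' @return a \linkS4class{SimilarityTransform}.
#' @export
similarityAbout <- function(center, alpha, s = 1, translation = c(0, 0)) {
  R <- s * matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2)
  t0 <- center - as.vector(R %*% center) + translation
  similarityTransform(alpha, t0[1], t0[2], s)
}

#' @rdname SimilarityTransform-class
#' @param x a \linkS4class{SimilarityTransform}.
#' @export
rotationAngle <- function(x) x@alpha

#' @rdname SimilarityTransform-class
#' @export
translation <- function(x) c(du = x@du, dv = x@dv)

#' @rdname SimilarityTransform-class
#' @export
scaleFactor <- function(x) x@s

#' Homogeneous 3 x 3 matrix of a similarity transform
#'
#' @param x a \linkS4class{SimilarityTransform}.
#' @return numeric 3 x 3 matrix whose upper-left block is
#'   \eqn{s [[\cos\alpha, -\sin\alpha], [\sin\alpha, \cos\alpha]]}.
#' @export
transformMatrix <- function(x) {
  ca <- cos(x@alpha); sa <- sin(x@alpha)
  matrix(c(x@s * ca, x@s * sa, 0,
           -x@s * sa, x@s * ca, 0,
           x@du, x@dv, 1), 3, 3)
}

#' Apply a similarity transform to points
#'
#' @param x a \linkS4class{SimilarityTransform}.
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyTransform <- function(x, pts) {
  p <- if (is.null(dim(pts))) matrix(pts, 1) else as.matrix(pts)
  ca <- cos(x@alpha); sa <- sin(x@alpha)
  cbind(x@s * (ca * p[, 1] - sa * p[, 2]) + x@du,
        x@s * (sa * p[, 1] + ca * p[, 2]) + x@dv)
}

#' @describeIn similarityTransform inverse transform (via \code{solve}).
#' @param a a \linkS4class{SimilarityTransform}.
#' @param b ignored.
#' @export
setMethod("solve", "SimilarityTransform", function(a, b, ...) {
  ca <- cos(a@alpha); sa <- sin(a@alpha)
  inv <- c(ca * a@du + sa * a@dv, -sa * a@du + ca * a@dv) / a@s
  similarityTransform(-a@alpha, -inv[1], -inv[2], 1 / a@s)
})

#' Compose two similarity transforms
#'
#' Returns the transform applying \code{b} first, then \code{a}.
#'
#' @param a,b \linkS4class{SimilarityTransform}s.
#' @return their composition \code{a o b}.
#' @export
composeTransforms <- function(a, b) {
  t0 <- applyTransform(a, c(b@du, b@dv))
  tf <- similarityTransform(a@alpha + b@alpha, t0[1], t0[2], a@s * b@s)
  tf@alpha <- atan2(sin(tf@alpha), cos(tf@alpha))
  tf
}

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: alpha %.4f rad (%.2f deg), t = (%.3f, %.3f), s = %.5f\n",
    object@alpha, object@alpha * 180 / pi, object@du, object@dv, object@s))
})

#' Write / read a transform as JSON
#'
#' The JSON object holds \code{alpha_rad, du, dv, s,
#' matrix_3x3_row_major}.
#'
#' @param x a \linkS4class{SimilarityTransform}.
#' @param path JSON file path.
#' @return \code{path} invisibly; \code{readTransformJSON} returns the
#'   transform.
#' @export
writeTransformJSON <- function(x, path) {
  jsonlite::write_json(
    list(alpha_rad = x@alpha, du = x@du, dv = x@dv, s = x@s,
         matrix_3x3_row_major = as.vector(t(transformMatrix(x)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformJSON
#' @export
readTransformJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarityTransform(o$alpha_rad, o$du, o$dv, o$s)
}
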