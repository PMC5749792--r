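#' Create a GrayImage
#'
#' @param pixels numeric matrix of intensities in \eqn{[0, 255]}
#'   (\code{[row, col]}, origin top-left).
#' @return a \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(128, 64, 64))
#' dim(img)
#' @export
GrayImage <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "double"
  new("GrayImage", m)
}

#' @describeIn GrayImage clamp values into [0, 255] and construct.
#' @export
clampGrayImage <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "double"
  m[m < 0] <- 0
  m[m > 255] <- 255
  new("GrayImage", m)
}

#' Read an image file as a GrayImage
#'
#' Reads PNG/TIFF/JPEG through EBImage; colour images are converted to
#' luminance. Intensities are rescaled from [0, 1] to [0, 255].
#'
#' @param path file path.
#' @return a \linkS4class{GrayImage}.
#' @export
readGrayImage <- function(path) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) > 2L)
    img <- EBImage::channel(img, "gray")
  # EBImage stores [x, y]; transpose to [row, col]
  m <- t(EBImage::imageData(img)) * 255
  clampGrayImage(m)
}

#' Write a GrayImage to an image file
#'
#' @param image a \linkS4class{GrayImage}.
#' @param path output path; format from the extension (png/tiff/jpeg).
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  EBImage::writeImage(EBImage::Image(t(image@.Data) / 255), path)
  invisible(path)
}

setMethod("show", "GrayImage", function(object) {
  px <- object@.Data
  cat(sprintf("GrayImage %d x %d (h x w), intensity range [%.3g, %.3g]\n",
              nrow(px), ncol(px), min(px), max(px)))
})

# minimum side length for detection (patch/border requirements)
.MIN_IMAGE_SIDE <- 32L

.checkImageSize <- function(image) {
  if (nrow(image) < .MIN_IMAGE_SIDE || ncol(image) < .MIN_IMAGE_SIDE)
    stop("image must be at least ", .MIN_IMAGE_SIDE, "x", .MIN_IMAGE_SIDE,
         " pixels for feature detection", call. = FALSE)
  invisible(TRUE)
}
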