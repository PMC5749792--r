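# Image pyramid and scale-ratio histogram screening of matches.

#' Build a Gaussian low-pass image pyramid
#'
#' Level 1 is the input; each further level is the previous one blurred
#' with an anti-alias Gaussian (sigma = 0.5 * factor by default) and
#' resampled by \code{1/factor} in both axes. Levels that would fall below
#' 32 px on a side are dropped with a warning. Because level sizes are
#' rounded to integers, the actual per-axis scale factors (level-0 extent
#' divided by level extent) are recorded and used to map keypoints back to
#' level-0 coordinates; the nominal \code{factor^(level-1)} scale is what
#' enters match scale ratios.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param nLevels number of levels (>= 1, default 4).
#' @param factor per-level downsampling ratio (> 1, default 2).
#' @param sigma anti-alias blur sigma (default \code{0.5 * factor}).
#' @return an \linkS4class{ImagePyramid}.
#' @export
buildPyramid <- function(image, nLevels = 4L, factor = 2,
                         sigma = 0.5 * factor) {
  stopifnot(is(image, "GrayImage"))
  if (nLevels < 1) stop("nLevels must be >= 1", call. = FALSE)
  if (factor <= 1) stop("factor must be > 1", call. = FALSE)
  levels <- list(image)
  h0 <- nrow(image); w0 <- ncol(image)
  for (l in seq_len(nLevels - 1L)) {
    prev <- levels[[l]]@.Data
    nh <- round(nrow(prev) / factor); nw <- round(ncol(prev) / factor)
    if (nh < .MIN_IMAGE_SIDE || nw < .MIN_IMAGE_SIDE) {
      warning("pyramid truncated at ", l, " level(s): next level below ",
              .MIN_IMAGE_SIDE, " px", call. = FALSE)
      break
    }
    blurred <- EBImage::gblur(prev, sigma = sigma)
    small <- EBImage::resize(blurred, w = nh, h = nw)  # EBImage: w = dim 1
    levels[[l + 1L]] <- clampGrayImage(small)
  }
  n <- length(levels)
  new("ImagePyramid",
      levels = levels,
      scale = factor^(seq_len(n) - 1),
      scaleX = vapply(levels, function(li) w0 / ncol(li), numeric(1)),
      scaleY = vapply(levels, function(li) h0 / nrow(li), numeric(1)))
}

#' @rdname ImagePyramid-class
#' @param x an \linkS4class{ImagePyramid}.
#' @export
pyramidLevels <- function(x) x@levels

setMethod("show", "ImagePyramid", function(object) {
  dims <- vapply(object@levels, function(l) sprintf("%dx%d", nrow(l), ncol(l)),
                 character(1))
  cat(sprintf("ImagePyramid: %d level(s) [%s], scales %s\n",
              length(object@levels), paste(dims, collapse = ", "),
              paste(signif(object@scale, 3), collapse = ", ")))
})

#' Scale-ratio histogram screening of matches
#'
#' Implements the scale-consistency filter: (1) a histogram of match scale
#' ratios on log-spaced bins (32 bins, minimum bin ratio-width 5%); (2)
#' matches whose ratio lies outside \code{[centre(peak) - omega,
#' centre(peak) + omega]} (ratio units) are rejected; (3) the dominant
#' ratio \code{d} is the mean scale ratio of the survivors (arithmetic
#' stand-in for the dominant mixture component's mean); (4) only survivors
#' with \code{0.6 d <= ratio <= 1.4 d} are retained. Peak ties break toward
#' the bin nearest ratio 1.
#'
#' @param matches match table with a \code{scaleRatio} column.
#' @param omega window half-width in ratio units; the recommended range is
#'   0.20-0.35 (default 0.25).
#' @param nBins number of histogram bins (default 32).
#' @return list with elements \code{matches} (retained rows, stage set to
#'   \code{"scale"}) and \code{histogram} (a \linkS4class{ScaleHistogram}).
#' @export
filterMatchesByScale <- function(matches, omega = 0.25, nBins = 32L) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("omega must be > 0", call. = FALSE)
  if (!nrow(matches)) {
    hist <- new("ScaleHistogram", breaks = numeric(0), counts = integer(0),
                peakBin = 0L, omega = omega, dominantRatio = NA_real_)
    return(list(matches = emptyMatches(), histogram = hist))
  }
  r <- matches$scaleRatio
  if (any(r <= 0)) stop("scale ratios must be > 0", call. = FALSE)
  lmin <- log(min(r)); lmax <- log(max(r))
  minWidth <- nBins * log(1.05)
  if (lmax - lmin < minWidth) {
    mid <- (lmin + lmax) / 2
    lmin <- mid - minWidth / 2; lmax <- mid + minWidth / 2
  }
  breaks <- exp(seq(lmin, lmax, length.out = nBins + 1L))
  bin <- findInterval(r, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nBins)
  centres <- sqrt(breaks[-1] * breaks[-(nBins + 1L)])
  peaks <- which(counts == max(counts))
  peak <- peaks[which.min(abs(log(centres[peaks])))]
  inWin <- r >= centres[peak] - omega & r <= centres[peak] + omega
  d <- mean(r[inWin])
  keep <- inWin & r >= 0.6 * d & r <= 1.4 * d
  out <- matches[keep, , drop = FALSE]
  if (nrow(out)) out$stage <- "scale"
  hist <- new("ScaleHistogram", breaks = breaks, counts = as.integer(counts),
              peakBin = as.integer(peak), omega = omega, dominantRatio = d)
  list(matches = out, histogram = hist)
}

#' @rdname ScaleHistogram-class
#' @param x a \linkS4class{ScaleHistogram}.
#' @export
dominantRatio <- function(x) x@dominantRatio

setMethod("show", "ScaleHistogram", function(object) {
  cat(sprintf(
    "ScaleHistogram: %d bins, peak bin %d, omega %.2f, dominant ratio %s\n",
    length(object@counts), object@peakBin, object@omega,
    format(object@dominantRatio, digits = 4)))
})

#' Write scale-histogram diagnostics
#'
#' Writes a \code{bin_center,count} CSV plus a JSON sidecar holding the
#' dominant ratio and retention window bounds.
#'
#' @param histogram a \linkS4class{ScaleHistogram}.
#' @param csvPath output CSV path; the sidecar replaces the extension with
#'   \code{.json}.
#' @return \code{csvPath}, invisibly.
#' @export
writeScaleHistogram <- function(histogram, csvPath) {
  n <- length(histogram@counts)
  centres <- if (n) sqrt(histogram@breaks[-1] * histogram@breaks[-(n + 1L)])
             else numeric(0)
  utils::write.csv(data.frame(bin_center = centres, count = histogram@counts),
                   csvPath, row.names = FALSE)
  d <- histogram@dominantRatio
  jsonlite::write_json(
    list(dominant_ratio = d, omega = histogram@omega,
         window = if (is.na(d)) NULL else c(0.6 * d, 1.4 * d)),
    sub("\\.[^.]*$", ".json", csvPath), auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
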