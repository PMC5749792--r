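# Plain-text interchange formats: keypoint CSV, descriptor hex, match JSON.

#' Write / read a keypoint table as CSV
#'
#' Columns \code{x, y, level, scale, response, orientation_rad}; pixel
#' coordinates are 0-based.
#'
#' @param keypoints keypoint table.
#' @param path CSV path.
#' @return \code{path} invisibly; \code{readKeypointCSV} returns the table.
#' @export
writeKeypointCSV <- function(keypoints, path) {
  out <- keypoints[, c("x", "y", "level", "scale", "response", "orientation")]
  names(out)[6] <- "orientation_rad"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKeypointCSV
#' @export
readKeypointCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  asKeypointTable(d$x, d$y, d$level, d$scale, d$response, d$orientation_rad)
}

#' Write / read descriptors as hex text
#'
#' One descriptor per line: 64 hex characters encoding 256 bits, bit order
#' big-endian within bytes (bit 1 of the pattern is the most significant
#' bit of the first byte). Lines pair 1:1 with the keypoint CSV rows.
#'
#' @param descriptors a \linkS4class{BinaryDescriptors}.
#' @param path output text path.
#' @return \code{path} invisibly; \code{readDescriptorsHex} returns the
#'   descriptors.
#' @export
writeDescriptorsHex <- function(descriptors, path) {
  bits <- descriptors@bits
  lines <- vapply(seq_len(ncol(bits)), function(i) {
    b <- matrix(bits[, i], nrow = 8L)           # one column per byte
    bytes <- as.integer(2^(7:0) %*% b)
    paste(sprintf("%02x", bytes), collapse = "")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeDescriptorsHex
#' @export
readDescriptorsHex <- function(path) {
  lines <- readLines(path)
  # decode: for each byte, most significant bit first
  dec <- function(ln) {
    bytes <- strtoi(substring(ln, seq(1, 63, 2), seq(2, 64, 2)), 16L)
    as.integer(unlist(lapply(bytes, function(b) bitwAnd(b %/% 2^(7:0), 1L))))
  }
  bits <- vapply(lines, dec, integer(256), USE.NAMES = FALSE)
  new("BinaryDescriptors", bits = matrix(bits, nrow = 256L))
}

#' Write matches as JSON
#'
#' Array of \code{{query_idx, train_idx, hamming, scale_ratio, stage}}
#' records (1-based indices into the keypoint tables); \code{stage} records
#' the last screening stage each pair passed.
#'
#' @param matches match table.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeMatchesJSON <- function(matches, path) {
  recs <- lapply(seq_len(nrow(matches)), function(i) {
    list(query_idx = matches$queryIdx[i], train_idx = matches$trainIdx[i],
         hamming = matches$hamming[i], scale_ratio = matches$scaleRatio[i],
         stage = matches$stage[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a registration result as JSON
#'
#' Schema: \code{stages} (per-stage match arrays), \code{transform},
#' \code{metrics} (stage counts).
#'
#' @param result a \linkS4class{RegistrationResult}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeResultJSON <- function(result, path) {
  stages <- lapply(result@stages, function(m)
    lapply(seq_len(nrow(m)), function(i)
      list(query_idx = m$queryIdx[i], train_idx = m$trainIdx[i],
           hamming = m$hamming[i], scale_ratio = m$scaleRatio[i],
           stage = m$stage[i])))
  tf <- result@transform
  jsonlite::write_json(
    list(stages = stages,
         transform = if (is.null(tf)) NULL else
           list(alpha_rad = tf@alpha, du = tf@du, dv = tf@dv, s = tf@s),
         metrics = lapply(result@stages, nrow),
         terminated = result@terminated),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
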