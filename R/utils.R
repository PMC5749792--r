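# internal helpers shared across modules

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# half-up decimal rounding (presentation rounding for percentages)
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# empty match table with the standard column contract
emptyMatches <- function() {
  data.frame(queryIdx = integer(0), trainIdx = integer(0),
             hamming = numeric(0), scaleRatio = numeric(0),
             quality = numeric(0), stage = character(0),
             stringsAsFactors = FALSE)
}

#' Build a match table
#'
#' Constructs the standard match table used throughout the pipeline:
#' columns \code{queryIdx, trainIdx, hamming, scaleRatio, quality, stage}.
#' Indices are 1-based positions in the keypoint tables.
#'
#' @param queryIdx,trainIdx keypoint indices.
#' @param hamming Hamming distances (optional).
#' @param scaleRatio query/train pyramid scale ratios (optional).
#' @param quality match quality for consensus ordering (optional).
#' @param stage last screening stage passed (optional).
#' @return a data.frame match table.
#' @export
asMatchTable <- function(queryIdx, trainIdx, hamming = NA_real_,
                         scaleRatio = NA_real_, quality = NA_real_,
                         stage = NA_character_) {
  if (!length(queryIdx)) return(emptyMatches())
  data.frame(queryIdx = as.integer(queryIdx), trainIdx = as.integer(trainIdx),
             hamming = as.numeric(hamming), scaleRatio = as.numeric(scaleRatio),
             quality = as.numeric(quality), stage = as.character(stage),
             stringsAsFactors = FALSE)
}

#' Build a keypoint table
#'
#' Constructs the standard keypoint table: columns \code{x, y, level,
#' scale, response, orientation}. Pixel coordinates are 0-based
#' (x = column, y = row, origin top-left), reported at level 0.
#'
#' @param x,y pixel coordinates.
#' @param level pyramid level index (0-based).
#' @param scale cumulative downsampling factor of the level.
#' @param response corner response score.
#' @param orientation dominant orientation in radians, \eqn{(-\pi, \pi]}.
#' @return a data.frame keypoint table.
#' @export
asKeypointTable <- function(x, y, level = 0L, scale = 1,
                            response = NA_real_, orientation = NA_real_) {
  n <- length(x)
  data.frame(x = as.numeric(x), y = as.numeric(y),
             level = rep_len(as.integer(level), n),
             scale = rep_len(as.numeric(scale), n),
             response = rep_len(as.numeric(response), n),
             orientation = rep_len(as.numeric(orientation), n),
             stringsAsFactors = FALSE)
}
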