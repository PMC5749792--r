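# Independent oracles and small fixture builders used across the suite.
# These re-derive expected results with deliberately different logic from
# the implementation under test.

# exhaustive FAST-9 segment-test oracle: per-pixel circular run check via
# run-length encoding on the doubled neighbour vector
fastOracleDetect <- function(P, xi) {
  dx <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1)
  dy <- c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)
  h <- nrow(P); w <- ncol(P)
  offLin <- dy + dx * h
  hits <- matrix(numeric(0), 0, 2)
  for (x in 4:(w - 3)) {
    base <- (x - 1L) * h
    for (y in 4:(h - 3)) {
      p <- base + y
      d <- P[p + offLin] - P[p]
      corner <- FALSE
      for (v in list(d > xi, d < -xi)) {
        if (sum(v) < 9) next
        r <- rle(c(v, v))
        if (any(r$values & r$lengths >= 9)) { corner <- TRUE; break }
      }
      if (corner) hits <- rbind(hits, c(x - 1, y - 1))
    }
  }
  hits
}

# brute-force greedy de-correlation oracle on a bit matrix
greedyOracle <- function(bits, k, thr0) {
  ord <- order(abs(colMeans(bits) - 0.5), seq_len(ncol(bits)))
  sel <- integer(0)
  thr <- thr0
  remaining <- ord
  repeat {
    stillLeft <- integer(0)
    for (j in remaining) {
      if (length(sel) >= k) break
      ok <- TRUE
      for (s in sel) {
        v <- suppressWarnings(stats::cor(bits[, j], bits[, s]))
        if (is.na(v)) v <- 1
        if (abs(v) >= thr) { ok <- FALSE; break }
      }
      if (ok) sel <- c(sel, j) else stillLeft <- c(stillLeft, j)
    }
    if (length(sel) >= k || !length(stillLeft)) break
    if (thr > 1.01) { sel <- c(sel, stillLeft[seq_len(k - length(sel))]); break }
    thr <- thr + 0.05
    remaining <- stillLeft
  }
  sel[seq_len(min(k, length(sel)))]
}

# exhaustive cost-matrix oracle for the geometric matcher (ratio mode)
geomOracle <- function(ptsA, ptsB, T = 0.8, sigma = 1) {
  prof <- function(P) lapply(seq_len(nrow(P)), function(i)
    sort(sqrt(colSums((t(P[-i, , drop = FALSE]) - P[i, ])^2))))
  pa <- prof(ptsA); pb <- prof(ptsB)
  Fm <- outer(seq_along(pa), seq_along(pb),
              Vectorize(function(i, j)
                sum(exp(-outer(pa[[i]], pb[[j]], "-")^2 / sigma^2))))
  qi <- integer(0); ti <- integer(0); fb <- numeric(0)
  for (i in seq_along(pa)) {
    o <- order(Fm[i, ], decreasing = TRUE)
    if (length(o) >= 2 && Fm[i, o[2]] / Fm[i, o[1]] >= T) next
    qi <- c(qi, i); ti <- c(ti, o[1]); fb <- c(fb, Fm[i, o[1]])
  }
  ord <- order(-fb, qi)
  keep <- sort(ord[!duplicated(ti[ord])])
  cbind(q = qi[keep], t = ti[keep])
}

# uniform random constellation with a minimum point separation
makeConstellation <- function(seed, n, box = 100, minSep = 8) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    p <- runif(2, 0, box)
    if (!nrow(pts) || min(sqrt(colSums((t(pts) - p)^2))) > minSep)
      pts <- rbind(pts, p)
  }
  pts
}

# naive double-loop box sum for one centred window (1-based centre)
naiveBoxSum <- function(P, r, c, side) {
  half <- side %/% 2
  sum(P[(r - half):(r + half), (c - half):(c + half)])
}

# bilinear sample of a GrayImage at 0-based (x, y)
bilinearAt <- function(img, x, y) {
  P <- if (is(img, "GrayImage")) img@.Data else img
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  (1 - fx) * (1 - fy) * P[y0 + 1, x0 + 1] +
    fx * (1 - fy) * P[y0 + 1, x0 + 2] +
    (1 - fx) * fy * P[y0 + 2, x0 + 1] +
    fx * fy * P[y0 + 2, x0 + 2]
}

# smooth random test image (band-limited noise)
makeTextureImage <- function(seed, size = 128, lo = 40, hi = 215) {
  set.seed(seed)
  m <- matrix(rnorm(size * size), size, size)
  m <- EBImage::gblur(m, sigma = 1.2)
  GrayImage((m - min(m)) / (max(m) - min(m)) * (hi - lo) + lo)
}
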