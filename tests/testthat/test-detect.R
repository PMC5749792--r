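test_that("a contrast-free image yields no FAST corners", {
  expect_equal(nrow(fast9Detect(GrayImage(matrix(128, 64, 64)), 40)), 0L)
})

test_that("FAST threshold validation", {
  img <- makeTextureImage(1, 64)
  expect_error(fast9Detect(img, 0), "xi")
  expect_error(fast9Detect(img, 300), "xi")
})

test_that("square corners are detected and match the brute-force oracle", {
  P <- matrix(0, 64, 64)
  P[21:40, 21:40] <- 255
  img <- GrayImage(P)
  kp <- fast9Detect(img, 40)
  expect_gt(nrow(kp), 0)
  corners <- rbind(c(20, 20), c(39, 20), c(20, 39), c(39, 39))
  dmin <- apply(as.matrix(kp[, c("x", "y")]), 1, function(p)
    min(sqrt(colSums((t(corners) - p)^2))))
  expect_true(all(dmin <= 3))
  ref <- fastOracleDetect(P, 40)
  expect_equal(unname(as.matrix(kp[order(kp$y, kp$x), c("x", "y")])),
               ref[order(ref[, 2], ref[, 1]), , drop = FALSE])
})

test_that("FAST equals the exhaustive oracle on textured images", {
  for (seed in 1:3) {
    img <- makeTextureImage(seed, 64)
    kp <- fast9Detect(img, 40)
    ref <- fastOracleDetect(img@.Data, 40)
    expect_equal(unname(as.matrix(kp[order(kp$y, kp$x), c("x", "y")])),
                 ref[order(ref[, 2], ref[, 1]), , drop = FALSE])
  }
})

test_that("detection is translation-equivariant away from borders", {
  img <- makeTextureImage(7, 96)
  P <- img@.Data
  dx <- 5L; dy <- 3L
  Q <- matrix(128, 96, 96)
  Q[(1 + dy):96, (1 + dx):96] <- P[1:(96 - dy), 1:(96 - dx)]
  k1 <- fast9Detect(img, 40)
  k2 <- fast9Detect(GrayImage(Q), 40)
  inner <- function(k, m) k[k$x >= m & k$x <= 95 - m & k$y >= m & k$y <= 95 - m, ]
  a <- inner(k1, 10)
  a$x <- a$x + dx; a$y <- a$y + dy
  b <- inner(k2, 10 + max(dx, dy))
  keyA <- paste(a$x, a$y); keyB <- paste(b$x, b$y)
  expect_true(all(keyB %in% keyA))
})

test_that("Harris selection ranks an ideal corner above an edge midpoint", {
  P <- matrix(0, 64, 64)
  P[25:64, 25:64] <- 200
  img <- GrayImage(P)
  cand <- asKeypointTable(x = c(24, 24), y = c(24, 45))  # corner, edge
  out <- harrisSelect(img, cand, nKeep = 2)
  expect_equal(out$y[1], 24)  # corner first
  expect_true(all(diff(out$response) <= 0))
})

test_that("Harris selection contract: subset, ordering, truncation", {
  img <- makeTextureImage(3, 96)
  cand <- fast9Detect(img, 40)
  out <- harrisSelect(img, cand, nKeep = 10)
  expect_lte(nrow(out), 10)
  expect_true(all(paste(out$x, out$y) %in% paste(cand$x, cand$y)))
  expect_true(all(diff(out$response) <= 0))
  expect_equal(nrow(harrisSelect(img, cand, nKeep = 0)), 0L)
  expect_error(harrisSelect(img, cand, nKeep = -1), "nKeep")
  one <- harrisSelect(img, cand[5, ], nKeep = 10)
  expect_equal(nrow(one), 1L)
  expect_true(is.finite(one$response))
})

test_that("orientation follows the intensity centroid", {
  # right half bright: mass toward +x, alpha = 0
  P <- matrix(0, 64, 64); P[, 33:64] <- 255
  kp <- asKeypointTable(x = 31, y = 31)
  expect_equal(computeOrientation(GrayImage(P), kp, 15)$orientation, 0)
  # bottom half bright: mass toward +y (down), alpha = pi/2
  P2 <- matrix(0, 64, 64); P2[33:64, ] <- 255
  expect_equal(computeOrientation(GrayImage(P2), kp, 15)$orientation, pi / 2)
  # point-symmetric patch: degenerate, alpha = 0 by convention
  expect_equal(computeOrientation(GrayImage(matrix(77, 64, 64)), kp, 15)$orientation, 0)
  # patch out of bounds
  expect_error(computeOrientation(GrayImage(P), asKeypointTable(2, 2), 15),
               "bounds")
})

test_that("orientation is equivariant under exact 90-degree rotation", {
  img <- makeTextureImage(11, 65)  # odd size: (32,32) is the exact centre
  P <- img@.Data
  kp <- asKeypointTable(x = 32, y = 32)
  a0 <- computeOrientation(img, kp, 15)$orientation
  # rotate content by +90 deg about the centre in (x, y-down) frame:
  # (x,y) -> (-y,x), i.e. Q[y'+1, x'+1] = P[y+1, x+1]
  n <- 65
  Q <- t(P)[, n:1]   # Q[r, c] = P[n+1-c, r]
  a90 <- computeOrientation(GrayImage(Q), kp, 15)$orientation
  d <- (a90 - a0 - pi / 2) %% (2 * pi)
  expect_lt(min(d, 2 * pi - d), 1e-12)
})

test_that("orientation rotates with the patch content", {
  # smooth off-centre blob; rotate content about the keypoint by 45 deg
  n <- 65
  X <- matrix(rep(0:(n - 1), each = n), n); Y <- matrix(rep(0:(n - 1), n), n)
  blob <- function(cx, cy) 200 * exp(-((X - cx)^2 + (Y - cy)^2) / 50)
  img <- clampGrayImage(blob(40, 32))
  kp <- asKeypointTable(x = 32, y = 32)
  a0 <- computeOrientation(img, kp, 15)$orientation
  phi <- pi / 4
  rot <- warpImage(img, similarityAbout(c(32, 32), phi))
  a1 <- computeOrientation(rot, kp, 15)$orientation
  d <- (a1 - a0 - phi) %% (2 * pi)
  expect_lt(min(d, 2 * pi - d), 0.05)
})

test_that("non-maximum suppression removes weaker duplicates", {
  img <- makeTextureImage(5, 64)
  cand <- fast9Detect(img, 30)
  out <- fastNonMaxSuppress(img, cand)
  expect_lte(nrow(out), nrow(cand))
  expect_true(all(paste(out$x, out$y) %in% paste(cand$x, cand$y)))
  # no surviving candidate has a strictly stronger 8-neighbour candidate
  R <- matrix(-Inf, 64, 64)
  R[cbind(cand$y + 1, cand$x + 1)] <- cand$response
  for (i in seq_len(nrow(out))) {
    nb <- R[(out$y[i]):(out$y[i] + 2), (out$x[i]):(out$x[i] + 2)]
    expect_gte(out$response[i], max(nb))
  }
})
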