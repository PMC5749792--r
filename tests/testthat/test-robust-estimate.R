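test_that("similarity transform algebra is consistent", {
  tf <- similarityTransform(pi / 5, 12, -3, 1.4)
  M <- transformMatrix(tf)
  expect_equal(M[1:2, 1:2],
               1.4 * matrix(c(cos(pi / 5), sin(pi / 5),
                              -sin(pi / 5), cos(pi / 5)), 2))
  pts <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  viaMatrix <- t(M %*% rbind(t(pts), 1))[, 1:2]
  expect_equal(applyTransform(tf, pts), viaMatrix)
  back <- applyTransform(solve(tf), applyTransform(tf, pts))
  expect_equal(back, pts)
  comp <- composeTransforms(solve(tf), tf)
  expect_equal(rotationAngle(comp), 0)
  expect_equal(unname(translation(comp)), c(0, 0))
  expect_equal(scaleFactor(comp), 1)
})

test_that("transform JSON round-trips", {
  tf <- similarityTransform(-0.3, 4.5, 6.25, 0.9)
  path <- tempfile(fileext = ".json")
  writeTransformJSON(tf, path)
  back <- readTransformJSON(path)
  expect_equal(rotationAngle(back), -0.3)
  expect_equal(unname(translation(back)), c(4.5, 6.25))
  expect_equal(scaleFactor(back), 0.9)
})

test_that("least-squares fit recovers exact transforms", {
  set.seed(3)
  src <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  expect_equal(rotationAngle(estimateTransform(src, src)), 0)
  expect_equal(scaleFactor(estimateTransform(src, src)), 1)
  truth <- similarityTransform(pi / 6, 5, -2)
  dst <- applyTransform(truth, src)
  fit <- estimateTransform(src, dst, allowScale = FALSE)
  expect_lt(abs(rotationAngle(fit) - pi / 6), 1e-9)
  expect_lt(max(abs(translation(fit) - c(5, -2))), 1e-9)
  truthS <- similarityTransform(-0.9, -11, 3, 1.7)
  fitS <- estimateTransform(src, applyTransform(truthS, src))
  expect_lt(abs(scaleFactor(fitS) - 1.7), 1e-9)
  expect_lt(abs(rotationAngle(fitS) + 0.9), 1e-9)
})

test_that("degenerate and reflective inputs behave as documented", {
  expect_error(estimateTransform(cbind(1, 2), cbind(3, 4)), "at least 2")
  expect_error(estimateTransform(rbind(c(5, 5), c(5, 5)),
                                 rbind(c(1, 1), c(9, 9))), "degenerate")
  # reflection: best proper rotation returned, with large residuals
  src <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  dst <- cbind(-src[, 1], src[, 2])
  fit <- estimateTransform(src, dst)
  expect_gt(scaleFactor(fit), 0)
  expect_gt(sqrt(mean(transformResiduals(fit, src, dst))), 1)
})

test_that("prosac on pure inliers terminates on the ratio condition", {
  cor0 <- synthCorrespondences(1, 40, similarityTransform(0.5, 8, -6))
  m <- asMatchTable(1:40, 1:40, quality = 40:1)
  res <- prosacFilter(m, cor0$src, cor0$dst, seed = 7)
  expect_equal(res@termination, "ratio")
  expect_true(all(inlierFlags(res)))
  direct <- estimateTransform(cor0$src, cor0$dst)
  expect_equal(rotationAngle(finalTransform(res)), rotationAngle(direct))
  expect_equal(translation(finalTransform(res)), translation(direct))
})

test_that("prosac defaults and preconditions", {
  expect_equal(eval(formals(prosacFilter)$eta0), 4L)
  cor0 <- synthCorrespondences(2, 3, similarityTransform())
  m <- asMatchTable(1:3, 1:3)
  expect_error(prosacFilter(m, cor0$src, cor0$dst), "eta0")
})

test_that("prosac recovers inliers under 40% gross contamination", {
  truth <- similarityTransform(0.4, 15, -9)
  okSeeds <- 0
  for (seed in 1:10) {
    cs <- synthCorrespondences(seed, 100, truth, outlierFrac = 0.4,
                               noiseSigma = 0.5)
    # outliers (last rows by construction) ranked last in quality
    m <- asMatchTable(1:100, 1:100, quality = rev(seq_len(100)))
    res <- prosacFilter(m, cs$src, cs$dst, seed = seed + 500)
    recovered <- sum(inlierFlags(res) & cs$inlier) / sum(cs$inlier)
    angErr <- abs(rotationAngle(finalTransform(res)) - 0.4) * 180 / pi
    if (recovered >= 0.95 && angErr < 1) okSeeds <- okSeeds + 1
    # post-hoc residual invariant: every flagged inlier within the bound
    expect_true(all(transformResiduals(finalTransform(res),
                                       cs$src, cs$dst)[inlierFlags(res)] <= 9))
  }
  expect_gte(okSeeds, 9)
})

test_that("consensus results are exactly reproducible under a seed", {
  cs <- synthCorrespondences(11, 60, similarityTransform(0.2, 3, 4),
                             outlierFrac = 0.3, noiseSigma = 0.5)
  m <- asMatchTable(1:60, 1:60, quality = rev(seq_len(60)))
  r1 <- prosacFilter(m, cs$src, cs$dst, seed = 99)
  r2 <- prosacFilter(m, cs$src, cs$dst, seed = 99)
  expect_identical(inlierFlags(r1), inlierFlags(r2))
  expect_identical(r1@history, r2@history)
  b1 <- ransacBaseline(m, cs$src, cs$dst, seed = 42)
  b2 <- ransacBaseline(m, cs$src, cs$dst, seed = 42)
  expect_identical(inlierFlags(b1), inlierFlags(b2))
})

test_that("ransac baseline equals prosac on clean data", {
  cs <- synthCorrespondences(5, 30, similarityTransform(-0.7, 2, 9))
  m <- asMatchTable(1:30, 1:30, quality = 30:1)
  rp <- prosacFilter(m, cs$src, cs$dst, seed = 1)
  rb <- ransacBaseline(m, cs$src, cs$dst, seed = 1)
  expect_identical(inlierFlags(rp), inlierFlags(rb))
  expect_true(all(inlierFlags(rb)))
})

test_that("progressive sampling reaches consensus no slower than uniform", {
  truth <- similarityTransform(0.3, -4, 11)
  iters <- function(res, target) {
    hit <- which(res@history >= target)
    if (length(hit)) hit[1] else res@nIterations + 1L
  }
  dP <- dR <- integer(0)
  for (seed in 1:15) {
    cs <- synthCorrespondences(seed + 40, 80, truth, outlierFrac = 0.5,
                               noiseSigma = 0.5)
    m <- asMatchTable(1:80, 1:80, quality = rev(seq_len(80)))
    target <- 0.9 * sum(cs$inlier)
    rp <- prosacFilter(m, cs$src, cs$dst, seed = seed, maxIter = 300,
                       tauGrow = 0, patience = 300L)
    rb <- ransacBaseline(m, cs$src, cs$dst, seed = seed, maxIter = 300)
    dP <- c(dP, iters(rp, target)); dR <- c(dR, iters(rb, target))
  }
  expect_lte(median(dP), median(dR))
})
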