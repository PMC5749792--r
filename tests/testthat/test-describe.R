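test_that("pattern generation is deterministic and in bounds", {
  p1 <- generatePattern(42, 15)
  p2 <- generatePattern(42, 15)
  expect_identical(p1@pairs, p2@pairs)
  expect_false(identical(generatePattern(0)@pairs, generatePattern(1)@pairs))
  expect_error(generatePattern(1, patchHalf = 4), "patchHalf")
  rmax <- 15 - 2  # patch half minus sub-window margin
  for (seed in 1:200) {
    p <- generatePattern(seed, 15)@pairs
    expect_true(all(p[, 1]^2 + p[, 2]^2 <= rmax^2))
    expect_true(all(p[, 3]^2 + p[, 4]^2 <= rmax^2))
  }
  expect_equal(nrow(p1@pairs), 256L)
})

test_that("pattern generation leaves the session RNG untouched", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generatePattern(7)); after <- runif(3)
  expect_identical(before, after)
})

test_that("greedy de-correlation matches a brute-force oracle", {
  set.seed(21)
  bits <- matrix(rbinom(100 * 5, 1, 0.5), 100, 5)
  expect_identical(greedyDecorrelate(bits, 5L, 0.3), greedyOracle(bits, 5L, 0.3))
  set.seed(22)
  bits2 <- matrix(rbinom(120 * 40, 1, 0.5), 120, 40)
  expect_identical(greedyDecorrelate(bits2, 20L, 0.2),
                   greedyOracle(bits2, 20L, 0.2))
})

test_that("duplicated tests are not both selected while alternatives remain", {
  set.seed(5)
  bits <- matrix(rbinom(80 * 12, 1, 0.5), 80, 12)
  bits[, 2] <- bits[, 1]  # exact duplicate pair
  sel <- greedyDecorrelate(bits, 8L, 0.3)
  expect_lte(sum(sel %in% c(1L, 2L)), 1L)
})

test_that("tied rankings preserve input order and all k survive", {
  # balanced columns: every |mean - 0.5| = 0, ranking tie -> input order
  set.seed(9)
  bits <- replicate(10, sample(rep(0:1, 25)))
  sel <- greedyDecorrelate(bits, 10L, 2)  # threshold above any correlation
  expect_identical(sel, 1:10)
})

test_that("learnPatternGreedy validates its inputs and selects k tests", {
  patches <- lapply(1:60, function(s) makeTextureImage(s, 33))
  cand <- generatePattern(1)@pairs
  expect_error(learnPatternGreedy(cand[1:10, ], patches, k = 256L), "candidate")
  pat <- learnPatternGreedy(cand[1:30, ], patches, k = 12L, corThreshold = 0.3)
  expect_s4_class(pat, "SamplingPattern")
  expect_equal(nrow(pat@pairs), 12L)
})

test_that("pattern steering matches the printed rotation matrix", {
  p <- generatePattern(7)
  expect_identical(steerPattern(p, 0)@pairs, p@pairs)
  s90 <- steerPattern(p, pi / 2)@pairs
  expect_equal(unname(s90[, "mx"]), unname(p@pairs[, "my"]))
  expect_equal(unname(s90[, "my"]), unname(-p@pairs[, "mx"]))
  expect_equal(unname(s90[, "nx"]), unname(p@pairs[, "ny"]))
  expect_equal(unname(s90[, "ny"]), unname(-p@pairs[, "nx"]))
  # direct 2x2 matrix-product oracle at alpha = 0.3
  a <- 0.3
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)  # rows of printed S'
  S <- t(p@pairs[, c("mx", "my")])
  expect_equal(unname(steerPattern(p, a)@pairs[, c("mx", "my")]),
               unname(round(t(R %*% S))))
})

test_that("box sums equal naive double-loop summation", {
  img <- makeTextureImage(31, 48)
  II <- georeg:::.integralImage(img@.Data)
  set.seed(1)
  for (i in 1:25) {
    r <- sample(5:44, 1); c <- sample(5:44, 1); side <- sample(c(3, 5, 7), 1)
    expect_equal(georeg:::.boxSums(II, r, c, side, 48, 48),
                 naiveBoxSum(img@.Data, r, c, side))
  }
})

test_that("a constant image yields the all-zero descriptor", {
  img <- GrayImage(matrix(100, 64, 64))
  kp <- asKeypointTable(x = 31, y = 31, orientation = 0.7)
  d <- describeKeypoints(img, kp)
  expect_equal(sum(descriptorBits(d)), 0)
})

test_that("each descriptor bit depends only on its pattern pair", {
  img <- makeTextureImage(13, 64)
  kp <- asKeypointTable(x = 31, y = 31, orientation = 0.4)
  p1 <- generatePattern(3)
  p2 <- p1
  p2@pairs[100, ] <- c(5L, -7L, -9L, 2L)
  b1 <- descriptorBits(describeKeypoints(img, kp, p1))
  b2 <- descriptorBits(describeKeypoints(img, kp, p2))
  expect_true(all(b1[-100] == b2[-100]))
})

test_that("intensity inversion complements the descriptor when no sums tie", {
  img <- makeTextureImage(17, 64)
  inv <- GrayImage(255 - img@.Data)
  kp <- asKeypointTable(x = c(25, 31, 38), y = c(30, 31, 26),
                        orientation = c(0, 1.1, -2.3))
  b <- descriptorBits(describeKeypoints(img, kp))
  bi <- descriptorBits(describeKeypoints(inv, kp))
  # a tie (both bits 0) can only arise when a pair's two steered sample
  # points round to the same pixel, making its box sums identical; no bit
  # may agree as 1, and genuine ties must be explained by coincidence
  expect_true(all(b + bi <= 1))
  tied <- which(b + bi == 0)
  p <- generatePattern()
  for (idx in tied) {
    pairRow <- ((idx - 1) %% 256) + 1
    kpi <- ((idx - 1) %/% 256) + 1
    step <- 2 * pi / 30
    a <- step * (round(kp$orientation[kpi] / step) %% 30)
    sp <- steerPattern(p, -a)@pairs[pairRow, ]
    expect_true(sp["mx"] == sp["nx"] && sp["my"] == sp["ny"])
  }
})

test_that("descriptors are rotation-covariant on smooth textures", {
  for (seed in 1:2) {
    fix <- synthTexturePair(seed, size = 160,
                            transform = similarityAbout(c(79.5, 79.5), pi / 6))
    kpA <- detectKeypoints(fix@imageA, nKeep = 60)
    mapped <- applyTransform(fix@truth, as.matrix(kpA[, c("x", "y")]))
    ok <- mapped[, 1] >= 20 & mapped[, 1] <= 139 &
          mapped[, 2] >= 20 & mapped[, 2] <= 139
    kpA <- kpA[ok, ]; mapped <- mapped[ok, , drop = FALSE]
    kpB <- asKeypointTable(x = round(mapped[, 1]), y = round(mapped[, 2]))
    kpB <- computeOrientation(fix@imageB, kpB)
    dA <- descriptorBits(describeKeypoints(fix@imageA, kpA))
    dB <- descriptorBits(describeKeypoints(fix@imageB, kpB))
    ham <- colSums(dA != dB)
    expect_lte(median(ham), 40)
  }
})

test_that("descriptor hex serialization round-trips", {
  set.seed(4)
  bits <- matrix(rbinom(256 * 7, 1, 0.5), 256, 7)
  d <- new("BinaryDescriptors", bits = bits)
  path <- tempfile(fileext = ".txt")
  writeDescriptorsHex(d, path)
  lines <- readLines(path)
  expect_equal(length(lines), 7L)
  expect_true(all(nchar(lines) == 64L))
  back <- readDescriptorsHex(path)
  expect_identical(descriptorBits(back), bits)
})
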