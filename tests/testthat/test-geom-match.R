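test_that("distance profiles reproduce Pythagorean arithmetic", {
  p <- distanceProfiles(rbind(c(0, 0), c(3, 0), c(0, 4)))
  expect_equal(profileList(p), list(c(3, 4), c(3, 5), c(4, 5)))
})

test_that("profiles are invariant under rigid motion and, normalized, scale", {
  pts <- makeConstellation(3, 9)
  tf <- similarityTransform(0.83, 40, -12)
  moved <- applyTransform(tf, pts)
  expect_equal(profileList(distanceProfiles(pts)),
               profileList(distanceProfiles(moved)))
  scaled <- pts * 3.7
  expect_equal(profileList(distanceProfiles(pts, normalize = TRUE)),
               profileList(distanceProfiles(scaled, normalize = TRUE)))
  nf <- distanceProfiles(pts, normalize = TRUE)
  expect_true(all(vapply(profileList(nf), function(d) abs(mean(d) - 1) < 1e-12,
                         logical(1))))
})

test_that("profile preconditions are enforced", {
  expect_error(distanceProfiles(rbind(c(1, 1))), "at least 2")
  expect_error(distanceProfiles(rbind(c(1, 1), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("geometric cost matches direct evaluation", {
  # (1,2) vs (1,3): exp(0) + exp(-4) + exp(-1) + exp(-1)
  expect_equal(geometricCost(c(1, 2), c(1, 3), sigma = 1),
               exp(0) + exp(-4) + exp(-1) + exp(-1))
  expect_equal(geometricCost(c(1, 2), c(1, 3)),
               geometricCost(c(1, 2), c(1, 3), sigma = 1))  # default sigma 1
  q <- c(2, 5, 9, 14)
  expect_gte(geometricCost(q, q), length(q))
  # literal printed form: positive exponent
  expect_equal(geometricCost(c(1, 2), c(1, 3), mode = "as-printed"),
               exp(0) + exp(4) + exp(1) + exp(1))
  expect_error(geometricCost(c(1), c(1), sigma = 0), "sigma")
  expect_error(geometricCost(numeric(0), c(1)), "non-empty")
})

test_that("geometric cost is symmetric and decreases with discrepancy", {
  set.seed(12)
  for (i in 1:10) {
    a <- sort(runif(6, 1, 50)); b <- sort(runif(8, 1, 50))
    expect_equal(geometricCost(a, b), geometricCost(b, a))
  }
  # moving one entry away from its best-matching counterpart lowers F
  a <- c(10, 20, 30)
  b <- c(10, 20, 30)
  base <- geometricCost(a, b)
  for (shift in c(0.5, 1, 2, 4)) {
    b2 <- c(10, 20 + shift, 30)
    expect_lt(geometricCost(a, b2), base)
  }
})

test_that("clean constellations are matched exactly and equal the oracle", {
  for (seed in 1:25) {
    n <- 5 + seed %% 8  # 5..12 points
    pts <- makeConstellation(seed, n)
    tf <- similarityTransform(runif(1, -pi, pi), runif(1, -20, 20),
                              runif(1, -20, 20))
    moved <- applyTransform(tf, pts)
    out <- geometricMatch(distanceProfiles(pts), distanceProfiles(moved))
    expect_equal(out$queryIdx, seq_len(n))
    expect_equal(out$trainIdx, seq_len(n))
    ref <- geomOracle(pts, moved)
    expect_equal(cbind(q = out$queryIdx, t = out$trainIdx), ref)
  }
})

test_that("mean-normalized profiles saturate the unit-width kernel", {
  # characterization of the default choice: with profiles divided by
  # their mean, sigma = 1 spans the whole normalized distance range, the
  # cost flattens, and the distinctiveness test rejects everything that
  # raw pixel profiles resolve perfectly
  for (seed in c(2, 5, 8)) {
    pts <- makeConstellation(seed, 8)
    moved <- applyTransform(similarityTransform(0.6, 12, -8), pts)
    raw <- geometricMatch(distanceProfiles(pts), distanceProfiles(moved))
    expect_equal(nrow(raw), 8L)
    norm <- geometricMatch(distanceProfiles(pts, normalize = TRUE),
                           distanceProfiles(moved, normalize = TRUE),
                           sigma = 1)
    expect_equal(nrow(norm), 0L)
  }
})

test_that("ambiguous candidates are rejected by the distinctiveness test", {
  prof <- sort(runif(5, 5, 60))
  A <- new("DistanceProfileSet", profiles = list(prof),
           normalized = FALSE, normFactors = 1)
  B <- new("DistanceProfileSet", profiles = list(prof, prof),
           normalized = FALSE, normFactors = c(1, 1))
  expect_equal(nrow(geometricMatch(A, B)), 0L)
  expect_equal(eval(formals(geometricMatch)$T), 0.8)
  expect_error(geometricMatch(A, B, T = 0), "T must")
  expect_error(geometricMatch(A, B, K = 1), "K must")
})

test_that("greedy assignment covers ratio-mode acceptances and conflicts", {
  pts <- makeConstellation(40, 10)
  moved <- applyTransform(similarityTransform(0.4, 7, -3), pts)
  pa <- distanceProfiles(pts); pb <- distanceProfiles(moved)
  ratioOut <- geometricMatch(pa, pb)
  greedyOut <- geometricMatch(pa, pb, assignment = "greedy")
  expect_true(all(paste(ratioOut$queryIdx, ratioOut$trainIdx) %in%
                  paste(greedyOut$queryIdx, greedyOut$trainIdx)))
  expect_true(all(greedyOut$accepted[match(
    paste(ratioOut$queryIdx, ratioOut$trainIdx),
    paste(greedyOut$queryIdx, greedyOut$trainIdx))]))
  expect_equal(anyDuplicated(greedyOut$queryIdx), 0L)
  expect_equal(anyDuplicated(greedyOut$trainIdx), 0L)
})

test_that("profile JSON dump is well-formed", {
  p <- distanceProfiles(makeConstellation(2, 5))
  path <- tempfile(fileext = ".json")
  writeProfilesJSON(p, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$owner_idx, 1:5)
})
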