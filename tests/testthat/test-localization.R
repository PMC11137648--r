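test_that("segment length is the Euclidean distance, translation-invariant", {
  expect_equal(segmentLength(pointChain(rbind(c(0, 0), c(3, 4))), 1), 5)
  expect_equal(segmentLength(pointChain(rbind(c(1, 1), c(4, 5))), 1), 5)
  expect_equal(segmentLength(pointChain(rbind(c(2, 2), c(2, 2), c(0, 0))), 1), 0)
  expect_error(segmentLength(pointChain(rbind(c(0, 0), c(1, 1))), 2),
               class = "spineDSS_validation_error")
})

test_that("distance constraint is a strict double inequality", {
  expect_true(distanceOk(straightChain(), 2))          # ratio 1
  ch <- pointChain(rbind(c(0, 0), c(0, 100), c(0, 150)))   # ratio 0.5
  expect_false(distanceOk(ch, 2))
  ch <- pointChain(rbind(c(0, 0), c(0, 100), c(0, 225)))   # ratio 1.25 exactly
  expect_false(distanceOk(ch, 2))
  ch <- pointChain(rbind(c(0, 0), c(0, 100), c(0, 220)))   # ratio 1.2
  expect_true(distanceOk(ch, 2))
  dup <- pointChain(rbind(c(0, 0), c(0, 0), c(0, 1)))
  expect_error(distanceOk(dup, 2), class = "spineDSS_geometry_error")
})

test_that("vertex angles match hand geometry", {
  expect_equal(angleAt(pointChain(rbind(c(0, 0), c(1, 0), c(2, 0))), 2), 180)
  expect_equal(angleAt(pointChain(rbind(c(0, 0), c(1, 1), c(2, 0))), 2), 90)
  expect_equal(angleAt(pointChain(rbind(c(0, 0), c(1, 0), c(1, 1))), 2), 90)
  dup <- pointChain(rbind(c(0, 0), c(0, 0), c(0, 1)))
  expect_error(angleAt(dup, 2), class = "spineDSS_geometry_error")
})

test_that("angle and ratio constraints are similarity-invariant", {
  set.seed(5)
  for (rep in 1:20) {
    pts <- cbind(runif(5, 0, 100), sort(runif(5, 0, 100)))
    ch <- pointChain(pts)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.5, 3); off <- runif(2, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    ch2 <- pointChain(sweep(s * pts %*% R, 2, -off))
    for (i in 2:4) {
      expect_equal(angleAt(ch, i), angleAt(ch2, i), tolerance = 1e-9)
      expect_identical(distanceOk(ch, i), distanceOk(ch2, i))
    }
  }
})

test_that("flagged landmarks match a brute-force constraint check", {
  cfg <- constraintConfig()
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    pts <- cbind(0, 70 * (seq_len(n) - 1))
    j <- sample(2:(n - 1), 1)
    pts[j, ] <- pts[j, ] + runif(2, -60, 60)
    ch <- pointChain(pts)
    # independent oracle: direct evaluation of the published inequalities
    brute <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      vi <- sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
      vp <- sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
      a <- pts[i - 1, ] - pts[i, ]; b <- pts[i + 1, ] - pts[i, ]
      ang <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
      if (!(vi / vp > 0.6 && vi / vp < 1.25)) brute[i] <- TRUE
      if (!(ang > 140 && ang <= 180)) brute[i] <- TRUE
    }
    flags <- chainViolations(ch, cfg)
    expect_identical(flags[2:(n - 1)], brute[2:(n - 1)])
  }
})

test_that("a clean chain is a fixed point of repair", {
  ch <- straightChain()
  r <- repairChain(ch)
  expect_identical(chainPoints(r$chain), chainPoints(ch))
  expect_length(r$repairedIndices, 0)
  expect_true(r$converged)
})

test_that("a laterally displaced landmark is restored from its neighbors", {
  ch <- straightChain()
  pts <- chainPoints(ch)
  pts[3, 1] <- 30
  r <- repairChain(pointChain(pts))
  expect_identical(r$repairedIndices, 3L)
  # midpoint of the untouched neighbors is the original collinear position
  expect_equal(unname(chainPoints(r$chain)[3, ]), c(0, 120))
  expect_equal(unname(chainPoints(r$chain)[-3, ]),
               unname(chainPoints(ch)[-3, ]))
})

test_that("repair is idempotent and degenerate chains are rejected", {
  set.seed(13)
  for (rep in 1:10) {
    pts <- cbind(0, 70 * (0:5))
    j <- sample(2:5, 1)
    pts[j, ] <- pts[j, ] + runif(2, -50, 50)
    r1 <- suppressWarnings(repairChain(pointChain(pts)))
    r2 <- suppressWarnings(repairChain(r1$chain))
    expect_identical(chainPoints(r2$chain), chainPoints(r1$chain))
  }
  expect_error(repairChain(pointChain(rbind(c(0, 0), c(0, 1), c(0, 2)))),
               class = "spineDSS_validation_error")
  # zig-zag: every vertex violates the angle constraint
  zig <- pointChain(cbind(c(0, 60, 0, 60, 0, 60), 40 * (0:5)))
  expect_error(repairChain(zig), class = "spineDSS_unrepairable")
})

test_that("the reference detector recovers phantom vertebrae within 4 mm", {
  ph <- sagCleanAllGrades()
  det <- detectVertebrae(phantomImage(ph), pixelSpacingMm = 0.2646)
  truth <- pointChain(vertebraCenters(ph), 0.2646)
  expect_identical(nPoints(det$chain), nrow(vertebraCenters(ph)))
  s <- localizationSensitivity(det$chain, truth, 4)
  expect_identical(s$sensitivity, 1)
  expect_error(detectVertebrae(matrix(0, 128, 128)),
               class = "spineDSS_chain_too_short")
})

test_that("repair restores a vertebra center corrupted by a bright artifact", {
  ph <- sagCleanAllGrades()
  img <- phantomImage(ph)
  ctr <- vertebraCenters(ph)
  # a bright streak fused to vertebra 3 drags its detected centroid dorsally
  occ <- img
  occ[round(ctr[3, 2]) + (-10:10), round(ctr[3, 1]) + (46:160)] <- 200
  det <- detectVertebrae(occ, pixelSpacingMm = 0.2646)
  expect_identical(nPoints(det$chain), 6L)
  truth <- pointChain(ctr, 0.2646)
  before <- localizationSensitivity(det$chain, truth, 4)$sensitivity
  expect_lt(before, 1)
  rep <- repairChain(det$chain)
  after <- localizationSensitivity(rep$chain, truth, 4)$sensitivity
  expect_identical(after, 1)
})

test_that("localization sensitivity counts greedy within-threshold matches", {
  truth <- straightChain(5, 80)
  expect_identical(localizationSensitivity(truth, truth, 4)$sensitivity, 1)
  expect_identical(localizationSensitivity(truth, truth, 4)$meanMm, 0)

  shifted <- pointChain(sweep(chainPoints(truth), 2, c(5 / 0.2646, 0), "+"))
  expect_identical(localizationSensitivity(shifted, truth, 4)$sensitivity, 0)

  missing <- pointChain(chainPoints(truth)[-2, , drop = FALSE])
  expect_identical(localizationSensitivity(missing, truth, 4)$sensitivity, 0.8)
})
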