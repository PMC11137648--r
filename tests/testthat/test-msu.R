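# symmetric synthetic marker set for geometry tests
symMarkers <- function() {
  msuMarkerSet(discCenter = c(100, 100), canalDorsal = c(100, 160),
               facetSupLeft = c(126, 140), facetSupRight = c(74, 140),
               facetInfLeft = c(130, 150), facetInfRight = c(70, 150),
               posteriorMargin = c(100, 120))
}

rotateAbout <- function(p, ctr, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  as.numeric(ctr + R %*% (p - ctr))
}

test_that("the grid is symmetric for mirror-symmetric markers", {
  g <- buildGrid(symMarkers())
  expect_equal(abs(g@tLeft), g@tRight)
  expect_equal(g@s0, 20)
  expect_equal(g@sIf, 45)   # facet midpoints at s = 45 on both sides
  expect_lt(g@s0, g@sIf)
})

test_that("grid scalars are invariant under rotation of all markers", {
  m <- symMarkers()
  g0 <- buildGrid(m)
  ctr <- m@discCenter
  rot <- msuMarkerSet(
    rotateAbout(m@discCenter, ctr, 30), rotateAbout(m@canalDorsal, ctr, 30),
    rotateAbout(m@facetSupLeft, ctr, 30), rotateAbout(m@facetSupRight, ctr, 30),
    rotateAbout(m@facetInfLeft, ctr, 30), rotateAbout(m@facetInfRight, ctr, 30),
    rotateAbout(m@posteriorMargin, ctr, 30))
  g1 <- buildGrid(rot)
  expect_equal(g1@s0, g0@s0, tolerance = 1e-9)
  expect_equal(g1@sIf, g0@sIf, tolerance = 1e-9)
  expect_equal(g1@tLeft, g0@tLeft, tolerance = 1e-9)
  expect_equal(g1@tRight, g0@tRight, tolerance = 1e-9)
})

test_that("marker-set invariants are validated", {
  m <- symMarkers()
  expect_error(msuMarkerSet(c(100, 100), c(100, 100), m@facetSupLeft,
                            m@facetSupRight, m@facetInfLeft, m@facetInfRight,
                            m@posteriorMargin),
               "canalDorsal")
  # margin beyond the canal dorsal point
  expect_error(msuMarkerSet(m@discCenter, m@canalDorsal, m@facetSupLeft,
                            m@facetSupRight, m@facetInfLeft, m@facetInfRight,
                            c(100, 170)),
               "posteriorMargin")
  # facet points on the wrong side of the AP axis
  expect_error(msuMarkerSet(m@discCenter, m@canalDorsal, m@facetSupRight,
                            m@facetSupLeft, m@facetInfLeft, m@facetInfRight,
                            m@posteriorMargin),
               "lateral")
})

test_that("apex selection follows max-s with central-lateral tie-break", {
  g <- buildGrid(symMarkers())
  m <- matrix(0, 200, 200)
  m[151, 101] <- 1   # single pixel (x=100, y=150)
  apex <- findApex(herniationMask(m), g)
  expect_equal(unname(apex$point), c(100, 150))

  # equal s, lateral -3 vs +1: the more central (+1 in t is x=99) wins
  m2 <- matrix(0, 200, 200)
  m2[151, 104] <- 1   # x=103 -> t = -3
  m2[151, 100] <- 1   # x=99  -> t = +1
  apex2 <- findApex(herniationMask(m2), g)
  expect_equal(unname(apex2$t), 1)

  expect_error(findApex(herniationMask(matrix(0, 10, 10)), g),
               class = "spineDSS_empty_mask")
})

test_that("the analytic rule reproduces hand-placed region labels", {
  g <- buildGrid(symMarkers())
  mk <- symMarkers()
  maskAt <- function(x, y) {
    m <- matrix(0, 220, 220); m[y + 1, x + 1] <- 1; herniationMask(m)
  }
  # 25% of the s0 -> sIf span, on the axis: size 1, zone A
  lab <- classifyMsu(mk, maskAt(100, round(100 + 20 + 0.25 * 25)))
  expect_identical(lab$size, 1L); expect_identical(lab$zone, "A")
  # beyond the intra-facet line and beyond tRight: size 3, zone C
  lab <- classifyMsu(mk, maskAt(60, 160))
  expect_identical(lab$size, 3L); expect_identical(lab$zone, "C")
  # at the lateral B/C boundary the more lateral zone is assigned
  g <- buildGrid(mk)
  lab <- classifyMsu(mk, maskAt(100 - round(g@tRight), 130))
  expect_identical(lab$zone, "C")
})

test_that("moving the apex dorsally never decreases the size grade", {
  mk <- symMarkers()
  sizes <- integer(0)
  for (y in seq(125, 170, by = 5)) {
    m <- matrix(0, 220, 220); m[y + 1, 101] <- 1
    sizes <- c(sizes, classifyMsu(mk, herniationMask(m))$size)
  }
  expect_true(all(diff(sizes) >= 0))
  expect_identical(sizes[1], 1L)
  expect_identical(sizes[length(sizes)], 3L)
})

test_that("classification is invariant under a joint rigid transform", {
  # rotate markers and mask by 90 degrees (exact on the pixel grid)
  mk <- symMarkers()
  S <- 220
  rot90pt <- function(p) c(S - 1 - p[2], p[1])
  mkR <- msuMarkerSet(rot90pt(mk@discCenter), rot90pt(mk@canalDorsal),
                      rot90pt(mk@facetSupLeft), rot90pt(mk@facetSupRight),
                      rot90pt(mk@facetInfLeft), rot90pt(mk@facetInfRight),
                      rot90pt(mk@posteriorMargin))
  for (pt in list(c(100, 150), c(70, 158), c(95, 130))) {
    m <- matrix(0, S, S); m[pt[2] + 1, pt[1] + 1] <- 1
    lab <- classifyMsu(mk, herniationMask(m))
    ptR <- rot90pt(pt)
    mR <- matrix(0, S, S); mR[ptR[2] + 1, ptR[1] + 1] <- 1
    labR <- classifyMsu(mkR, herniationMask(mR))
    expect_identical(labR$size, lab$size)
    expect_identical(labR$zone, lab$zone)
  }
})

test_that("analytic labels agree with the rasterized region map", {
  r <- msuClosedLoop(nCases = 54, seed = 17)
  expect_identical(r$oracleAgreement, 1)
  expect_identical(r$truthRecovery, 1)
})

test_that("the reference segmenter recovers phantom herniations", {
  for (s in 1:4) {
    ax <- generateAxial(phantomConfig(imageSize = 256, seed = 70 + s),
                        list(size = ((s - 1) %% 3) + 1, zone = c("A", "C", "B", "A")[s]))
    seg <- segmentHerniation(phantomImage(ax), phantomMarkers(ax))
    expect_gte(dsc(confusionFromMasks(seg, phantomMaskTruth(ax))), 0.9)
  }
  # constant image: empty mask plus a warning, not an error
  mk <- phantomMarkers(generateAxial(phantomConfig(imageSize = 256, seed = 1), NULL))
  expect_warning(m <- segmentHerniation(matrix(50, 256, 256), mk),
                 class = "spineDSS_empty_segmentation")
  expect_identical(sum(maskMatrix(m)), 0)
  # identity segmenter reproduces the truth exactly
  ax <- generateAxial(phantomConfig(imageSize = 256, seed = 99), list(size = 2, zone = "A"))
  seg <- segmentHerniation(phantomImage(ax), phantomMarkers(ax),
                           identitySegmenter(phantomMaskTruth(ax)))
  expect_identical(dsc(confusionFromMasks(seg, phantomMaskTruth(ax))), 1)
})
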