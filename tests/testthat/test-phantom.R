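test_that("identical config and seed reproduce phantoms bit-identically", {
  cfg <- phantomConfig(seed = 42)
  sp <- discSpecs(c(1, 3, 2, 5, 4), herniated = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  a <- generateSagittal(cfg, sp)
  b <- generateSagittal(cfg, sp)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(discTruth(a), discTruth(b))
  expect_identical(vertebraCenters(a), vertebraCenters(b))

  axA <- generateAxial(phantomConfig(imageSize = 256, seed = 9), list(size = 2, zone = "B"))
  axB <- generateAxial(phantomConfig(imageSize = 256, seed = 9), list(size = 2, zone = "B"))
  expect_identical(phantomImage(axA), phantomImage(axB))
  expect_identical(maskMatrix(phantomMaskTruth(axA)), maskMatrix(phantomMaskTruth(axB)))
})

test_that("disc mean intensity strictly decreases with Pfirrmann grade", {
  ph <- sagCleanAllGrades()   # grades 1..5 in order, noise-free
  img <- phantomImage(ph)
  means <- vapply(discRegions(ph), function(r) mean(img[r$disc]), 0)
  expect_true(all(diff(means) < 0))

  # every grade-1 disc outshines every grade-5 disc under the same seed
  ph5 <- generateSagittal(phantomConfig(noiseSigma = 0, seed = 11), discSpecs(rep(5, 5)))
  m5 <- vapply(discRegions(ph5), function(r) mean(phantomImage(ph5)[r$disc]), 0)
  ph1 <- generateSagittal(phantomConfig(noiseSigma = 0, seed = 11), discSpecs(rep(1, 5)))
  m1 <- vapply(discRegions(ph1), function(r) mean(phantomImage(ph1)[r$disc]), 0)
  expect_true(min(m1) > max(m5))
})

test_that("grade-5 discs have reduced height", {
  ph <- sagCleanAllGrades()
  img <- phantomImage(ph)
  heightOf <- function(r) {
    yy <- (r$disc - 1) %% nrow(img)
    diff(range(yy))
  }
  h <- vapply(discRegions(ph), heightOf, 0)
  expect_lt(h[5], 0.7 * h[1])
})

test_that("requested herniations produce exactly the requested protrusions", {
  ph <- sagHerniated()   # herniated = T,F,T,F,F
  nProt <- vapply(discRegions(ph), function(r) length(r$protrusion), 0L)
  expect_identical(nProt > 0, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(sum(nProt > 0), 2L)
})

test_that("phantom configuration invariants are enforced", {
  expect_error(phantomConfig(imageSize = 64), class = "spineDSS_validation_error")
  expect_error(phantomConfig(nVertebrae = 2), class = "spineDSS_validation_error")
  expect_error(phantomConfig(pixelSpacingMm = 0), class = "spineDSS_validation_error")
  expect_error(generateSagittal(phantomConfig(), discSpecs(1:3)),
               class = "spineDSS_validation_error")
  expect_error(discSpecs(c(1, 6)), class = "spineDSS_validation_error")
  expect_error(discSpecs(1:3, msuSize = c(1, NA, NA)),
               class = "spineDSS_validation_error")
  expect_error(generateAxial(phantomConfig(), list(size = 4, zone = "A")),
               class = "spineDSS_validation_error")
})

test_that("axial phantom without target has an empty mask and no label", {
  ax <- generateAxial(phantomConfig(imageSize = 256, seed = 3), NULL)
  expect_identical(sum(maskMatrix(phantomMaskTruth(ax))), 0)
  expect_length(phantomMsuTruth(ax), 0)
})

test_that("planted 1-A apex sits in the ventral central band of the grid", {
  for (s in c(5, 6, 7)) {
    ax <- generateAxial(phantomConfig(imageSize = 256, seed = s), list(size = 1, zone = "A"))
    grid <- buildGrid(phantomMarkers(ax))
    apex <- findApex(phantomMaskTruth(ax), grid)
    frac <- (apex$s - grid@s0) / (grid@sIf - grid@s0)
    expect_gt(frac, 0); expect_lt(frac, 0.5)
    span <- grid@tRight - grid@tLeft
    expect_gt(apex$t, grid@tLeft / 2)
    expect_lt(apex$t, grid@tRight / 2)
    expect_lt(abs(apex$t), span / 4)
  }
})

test_that("planted labels are recovered by the analytic classifier", {
  combos <- expand.grid(size = 1:3, zone = c("A", "B", "C"), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    ax <- generateAxial(phantomConfig(imageSize = 256, seed = 30 + k),
                        list(size = combos$size[k], zone = combos$zone[k]))
    lab <- classifyMsu(phantomMarkers(ax), phantomMaskTruth(ax))
    expect_identical(lab$size, as.integer(combos$size[k]))
    expect_identical(lab$zone, combos$zone[k])
  }
})
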