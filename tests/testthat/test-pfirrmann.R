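test_that("the grading crop is centered on the disc and translation-equivariant", {
  # intensity ramp along y lets us locate the sampled band
  img <- matrix(rep(0:199, times = 200), 200, 200)
  p1 <- c(100, 60); p2 <- c(100, 120)
  patch <- cropPfirrmannRoi(img, p1, p2)
  expect_identical(dim(patch), c(96L, 48L))
  # columns run along the inter-center line: first column near y=60, last near y=120
  expect_lt(abs(mean(patch[, 1]) - 60.625), 1.5)
  expect_lt(abs(mean(patch[, 48]) - 119.375), 1.5)

  shifted <- cropPfirrmannRoi(rbind(img[3:200, ], img[1:2, ]) , p1 - c(0, 2), p2 - c(0, 2))
  expect_equal(shifted, patch, tolerance = 1e-9)
  expect_error(cropPfirrmannRoi(img, c(10, 10), c(10, 10)),
               class = "spineDSS_geometry_error")
})

test_that("phantom grading crops reflect the grade intensity mapping", {
  ph <- sagCleanAllGrades()
  ctr <- vertebraCenters(ph)
  for (i in c(1, 3, 5)) {
    patch <- cropPfirrmannRoi(phantomImage(ph), ctr[i, ], ctr[i + 1, ])
    central <- patch[37:60, 20:29]   # nucleus region of the disc
    g <- discTruth(ph)$pfirrmann[i]
    expected <- (230 - 35 * (g - 1)) + 20 * (1 - (g - 1) / 4)
    expect_lt(abs(mean(central) - expected), 12)
  }
})

test_that("training validates grades and architecture", {
  X <- matrix(runif(10 * 572), 10, 572)
  expect_error(trainPfirrmann(X, c(1, 1, 2, 2, 3, 3, 4, 4, 4, 4)),
               class = "spineDSS_training_error")
  cfgBad <- pfirrmannMlpConfig()
  cfgBad$layerSizes <- c(572, 100, 5)
  expect_error(trainPfirrmann(X, rep(1:5, 2), cfgBad),
               class = "spineDSS_validation_error")
  expect_error(pfirrmannMlpConfig(epochs = 0), class = "spineDSS_validation_error")
})

test_that("training is a pure function of data, config and seed", {
  set.seed(6)
  X <- matrix(runif(50 * 572), 50, 572)
  y <- rep(1:5, each = 10)
  cfg <- pfirrmannMlpConfig(epochs = 5, seed = 3)
  m1 <- trainPfirrmann(X, y, cfg)
  m2 <- trainPfirrmann(X, y, cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@biases, m2@biases)
  expect_identical(m1@lossHistory, m2@lossHistory)
})

test_that("training loss decreases over epoch-averaged windows", {
  set.seed(8)
  X <- matrix(runif(100 * 572), 100, 572)
  y <- rep(1:5, each = 20)
  X[, 1] <- y + rnorm(100, 0, 0.1)   # a learnable signal
  m <- trainPfirrmann(X, y, pfirrmannMlpConfig(epochs = 40, seed = 2))
  expect_gt(mean(m@lossHistory[1:10]), mean(tail(m@lossHistory, 10)))
})

test_that("predictions are proper probabilities with lowest-grade tie-break", {
  set.seed(9)
  X <- matrix(runif(50 * 572), 50, 572)
  y <- rep(1:5, 10)
  m <- trainPfirrmann(X, y, pfirrmannMlpConfig(epochs = 3, seed = 1))
  pr <- predictPfirrmann(m, X[1, ])
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-9)
  expect_true(pr$grade %in% 1:5)
  expect_error(predictPfirrmann(new("MlpModel"), X[1, ]),
               class = "spineDSS_state_error")

  # exact tie (all-zero weights): the lowest grade wins
  tie <- new("MlpModel",
             weights = list(matrix(0, 572, 5)), biases = list(rep(0, 5)),
             norm = list(mean = rep(0, 572), sd = rep(1, 572)),
             classes = as.character(1:5),
             config = list(layerSizes = c(572L, 5L)),
             lossHistory = 0, featureMeta = list())
  pr <- predictPfirrmann(tie, X[2, ])
  expect_identical(pr$grade, 1L)
  expect_equal(unname(pr$probabilities), rep(0.2, 5))
})

test_that("held-out accuracy rises with phantom class separability", {
  accs <- vapply(c(60, 25, 0), function(sig) {
    # render the same disc set at decreasing noise (increasing separability)
    local({
      patches <- list(); grades <- integer(0)
      for (k in 1:12) {
        prm <- spineDSS:::withSeed(40 + 7000L + k, list(g = sample(1:5)))
        cfg <- phantomConfig(noiseSigma = sig, seed = 40 + k)
        ph <- generateSagittal(cfg, discSpecs(prm$g))
        ctr <- vertebraCenters(ph)
        for (i in 1:5) {
          patches[[length(patches) + 1]] <-
            cropPfirrmannRoi(phantomImage(ph), ctr[i, ], ctr[i + 1, ])
          grades <- c(grades, prm$g[i])
        }
      }
      X <- do.call(rbind, lapply(patches, buildFeatureVector))
      te <- seq(1, 60, by = 4)
      m <- trainPfirrmann(X[-te, ], grades[-te],
                          pfirrmannMlpConfig(epochs = 60, seed = 40))
      mean(predictPfirrmann(m, X[te, ]) == grades[te])
    })
  }, 0)
  expect_true(all(diff(accs) >= 0))
})
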