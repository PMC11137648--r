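# Phantom-based closed-loop validation experiments. Each experiment
# generates seeded phantoms, runs the corresponding pipeline stage, and
# measures recovery against the phantoms' exact ground truth. These are the
# package's own end-to-end checks; the vignette discusses what they do and
# do not show about real MRI.

#' Constraint-repair closed loop
#'
#' For each case: generate a sagittal phantom, displace one interior
#' ground-truth vertebra center by \code{displaceMm} in a random direction,
#' run [repairChain()], and score [localizationSensitivity()] against the
#' true centers at the 4-mm threshold. Also verifies idempotence (repairing
#' the repaired chain changes nothing).
#'
#' @param nCases number of phantoms; default 200.
#' @param seed base RNG seed; case k uses seed + k.
#' @param displaceMm outlier displacement magnitude in mm; default 12
#'   (comfortably above the 8-mm outlier definition).
#' @param thresholdMm sensitivity threshold; default 4.
#' @return list(sensitivity, idempotent, perCase).
#' @export
repairClosedLoop <- function(nCases = 200L, seed = 1L, displaceMm = 12,
                             thresholdMm = 4) {
  sens <- numeric(nCases)
  idem <- logical(nCases)
  for (k in seq_len(nCases)) {
    cfg <- phantomConfig(noiseSigma = 0, seed = seed + k)
    ph <- generateSagittal(cfg, discSpecs(rep(2, cfg$nVertebrae - 1)))
    truth <- pointChain(vertebraCenters(ph), cfg$pixelSpacingMm)
    pts <- chainPoints(truth)
    prm <- withSeed(seed + k, {
      i <- sample(2:(nrow(pts) - 1), 1)
      ang <- stats::runif(1, 0, 2 * pi)
      list(i = i, ang = ang)
    })
    d <- displaceMm / cfg$pixelSpacingMm
    pts[prm$i, ] <- pts[prm$i, ] + d * c(cos(prm$ang), sin(prm$ang))
    rep1 <- repairChain(pointChain(pts, cfg$pixelSpacingMm))
    sens[k] <- localizationSensitivity(rep1$chain, truth, thresholdMm)$sensitivity
    rep2 <- repairChain(rep1$chain)
    idem[k] <- identical(chainPoints(rep2$chain), chainPoints(rep1$chain))
  }
  list(sensitivity = mean(sens), idempotent = all(idem), perCase = sens)
}

#' MSU oracle-equivalence and label-recovery sweep
#'
#' Generates axial phantoms with planted (size, zone) labels cycling over
#' all 9 combinations and measures (a) agreement of the analytic
#' [classifyMsu()] with a lookup in the brute-force
#' [rasterizeMsuRegions()] map at the apex pixel, (b) recovery of the
#' planted label, and (c) the DSC of the reference threshold segmenter
#' against the ground-truth mask.
#'
#' @param nCases number of phantoms; default 1000.
#' @param seed base seed.
#' @param imageSize axial raster size; default 256 (geometry scales).
#' @return list(oracleAgreement, truthRecovery, meanDsc, minDsc, perCase).
#' @export
msuClosedLoop <- function(nCases = 1000L, seed = 1L, imageSize = 256L) {
  combos <- expand.grid(size = 1:3, zone = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
  agree <- logical(nCases)
  recover <- logical(nCases)
  dscs <- numeric(nCases)
  for (k in seq_len(nCases)) {
    tg <- combos[(k - 1) %% nrow(combos) + 1, ]
    cfg <- phantomConfig(imageSize = imageSize, seed = seed + k)
    ax <- generateAxial(cfg, list(size = tg$size, zone = tg$zone), seed = seed + k)
    markers <- phantomMarkers(ax)
    truthMask <- phantomMaskTruth(ax)
    lab <- classifyMsu(markers, truthMask)
    # independent route: paint all 9 regions, look up the apex pixel
    grid <- buildGrid(markers)
    regions <- rasterizeMsuRegions(grid, dim(phantomImage(ax)))
    apex <- findApex(truthMask, grid)
    code <- regions[apex$point["y"] + 1, apex$point["x"] + 1]
    agree[k] <- (lab$size == code %/% 10) &&
      (lab$zone == c("A", "B", "C")[code %% 10])
    tr <- phantomMsuTruth(ax)
    recover[k] <- (lab$size == tr$size) && (lab$zone == tr$zone)
    seg <- suppressWarnings(segmentHerniation(phantomImage(ax), markers))
    dscs[k] <- dsc(confusionFromMasks(seg, truthMask))
  }
  list(oracleAgreement = mean(agree), truthRecovery = mean(recover),
       meanDsc = mean(dscs), minDsc = min(dscs),
       perCase = data.frame(agree = agree, recover = recover, dsc = dscs))
}

# Generate a balanced set of graded disc patches from sagittal phantoms:
# each phantom carries one disc of every grade (positions shuffled).
gradedDiscPatches <- function(nPerGrade = 100L, seed = 1L, herniationRate = 0) {
  patches <- list(); grades <- integer(0); herniated <- logical(0)
  rois <- list()
  nPh <- nPerGrade
  for (k in seq_len(nPh)) {
    prm <- withSeed(seed + 7000L + k, {
      list(g = sample(1:5), h = stats::runif(5) < herniationRate)
    })
    cfg <- phantomConfig(seed = seed + k)
    ph <- generateSagittal(cfg, discSpecs(prm$g, herniated = prm$h))
    ctr <- vertebraCenters(ph)
    for (i in 1:5) {
      patches[[length(patches) + 1]] <-
        cropPfirrmannRoi(phantomImage(ph), ctr[i, ], ctr[i + 1, ])
      rois[[length(rois) + 1]] <-
        cropDiscRoi(phantomImage(ph), ctr[i, ], ctr[i + 1, ], levelIndex = i)
      grades <- c(grades, prm$g[i])
      herniated <- c(herniated, prm$h[i])
    }
  }
  list(patches = patches, rois = rois, grades = grades, herniated = herniated)
}

#' Pfirrmann grading closed loop
#'
#' Generates \code{nPerGrade} phantom discs per grade, extracts the
#' 572-dimensional descriptor from each grading crop, trains the
#' 572-300-150-5 MLP on a stratified 80/20 split, and reports held-out
#' accuracy, the per-grade table, and the fraction of misclassifications
#' landing on an adjacent grade. With \code{permuteLabels} the training
#' labels are shuffled to establish the chance-level null.
#'
#' @param nPerGrade discs per grade; default 100.
#' @param seed base seed.
#' @param permuteLabels train on randomly permuted labels; default FALSE.
#' @param epochs SGD epochs; default 200.
#' @return list(accuracy, adjacentErrorFraction, perClass, table, model).
#' @export
pfirrmannClosedLoop <- function(nPerGrade = 100L, seed = 1L,
                                permuteLabels = FALSE, epochs = 200L) {
  data <- gradedDiscPatches(nPerGrade, seed)
  X <- do.call(rbind, lapply(data$patches, buildFeatureVector))
  y <- data$grades
  idx <- withSeed(seed + 31L, {
    unlist(lapply(1:5, function(g) {
      ofg <- which(y == g)
      sample(ofg, round(0.2 * length(ofg)))
    }))
  })
  trX <- X[-idx, , drop = FALSE]; trY <- y[-idx]
  teX <- X[idx, , drop = FALSE]; teY <- y[idx]
  if (permuteLabels)
    trY <- withSeed(seed + 77L, sample(trY))
  model <- trainPfirrmann(trX, trY,
                          pfirrmannMlpConfig(epochs = epochs, seed = seed))
  pred <- predictPfirrmann(model, teX)
  mm <- multiclassMetrics(as.integer(pred), teY, classes = 1:5)
  errs <- which(as.integer(pred) != teY)
  adjacent <- if (length(errs)) mean(abs(as.integer(pred)[errs] - teY[errs]) == 1) else 1
  list(accuracy = mm$accuracy, adjacentErrorFraction = adjacent,
       nErrors = length(errs), perClass = mm$perClass, table = mm$table,
       model = model, nTest = length(teY))
}

#' Herniation-diagnosis closed loop
#'
#' Generates phantom discs with a 50% herniation rate across mixed grades,
#' crops the posterior 44-px ROI for each, trains the reference two-class
#' head on a stratified 80/20 split, and reports held-out accuracy.
#'
#' @param nPerClass approximate ROIs per class; default 200.
#' @param seed base seed.
#' @param permuteLabels train on shuffled labels for the null; default FALSE.
#' @return list(accuracy, nTest, model, confusion).
#' @export
diagnosisClosedLoop <- function(nPerClass = 200L, seed = 1L,
                                permuteLabels = FALSE) {
  data <- gradedDiscPatches(nPerGrade = ceiling(2 * nPerClass / 5), seed,
                            herniationRate = 0.5)
  y <- factor(ifelse(data$herniated, "herniated", "normal"),
              levels = c("normal", "herniated"))
  idx <- withSeed(seed + 53L, {
    unlist(lapply(levels(y), function(cl) {
      ofc <- which(y == cl)
      sample(ofc, round(0.2 * length(ofc)))
    }))
  })
  trRois <- data$rois[-idx]; trY <- y[-idx]
  teRois <- data$rois[idx]; teY <- y[idx]
  if (permuteLabels)
    trY <- withSeed(seed + 91L, sample(trY))
  model <- trainDiagnosisModel(trRois, trY, seed = seed)
  pred <- vapply(teRois, function(r) classifyHerniation(r, model)$label, "")
  list(accuracy = mean(pred == as.character(teY)), nTest = length(teY),
       model = model,
       confusion = table(pred = pred, truth = as.character(teY)))
}
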