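# Herniation diagnosis from the posterior disc ROI.
#
# The ROI is an oriented rectangle sitting on the line that connects the
# localization points of two adjacent vertebral bodies and extending a fixed
# 44 pixels dorsally -- the posterior half of the disc, where herniations
# protrude. The classifier is pluggable; the reference implementation feeds
# the shared HPI/LBP/PHOG descriptor into a two-class softmax head.

#' Posterior ROI configuration
#'
#' @param stripWidthPx fixed dorsal extent of the ROI in source pixels;
#'   default 44.
#' @param outputSize c(alongSegment, dorsal) resampled patch size; default
#'   c(64, 44).
#' @param dorsalDirection 2-vector pointing dorsally; normalized internally.
#' @export
roiConfig <- function(stripWidthPx = 44, outputSize = c(64L, 44L),
                      dorsalDirection = c(1, 0)) {
  if (stripWidthPx <= 0)
    stopf("spineDSS_validation_error", "stripWidthPx must be positive")
  list(stripWidthPx = stripWidthPx, outputSize = as.integer(outputSize),
       dorsalDirection = unitVec(as.numeric(dorsalDirection)))
}

#' Crop the posterior disc ROI
#'
#' The oriented rectangle has its long side on the segment from
#' \code{pUpper} to \code{pLower} (the adjacent vertebra localization
#' points) and its short side of \code{stripWidthPx} pixels extending from
#' that line in the dorsal direction. Samples outside the image read 0; the
#' patch is produced by rotated bilinear resampling.
#'
#' @param image grayscale matrix.
#' @param pUpper,pLower adjacent vertebra centers (x, y).
#' @param cfg a [roiConfig()].
#' @param levelIndex 1-based disc level stored on the ROI.
#' @return A [DiscROI-class].
#' @export
cropDiscRoi <- function(image, pUpper, pLower, cfg = roiConfig(),
                        levelIndex = 1L) {
  d <- pLower - pUpper
  len <- sqrt(sum(d^2))
  if (len == 0)
    stopf("spineDSS_geometry_error", "pUpper and pLower coincide")
  d1 <- d / len
  # short side perpendicular to the inter-vertebra line, on the dorsal side
  perp <- rot90vec(d1)
  sgn <- sum(perp * cfg$dorsalDirection)
  if (abs(sgn) < 1e-9)
    stopf("spineDSS_geometry_error",
          "dorsal direction is parallel to the inter-vertebra segment")
  d2 <- perp * sign(sgn)
  w <- cfg$stripWidthPx
  corners <- rbind(pUpper, pLower, pLower + w * d2, pUpper + w * d2)
  if (all(corners[, 1] < 0) || all(corners[, 1] > ncol(image) - 1) ||
      all(corners[, 2] < 0) || all(corners[, 2] > nrow(image) - 1))
    stopf("spineDSS_geometry_error", "ROI rectangle lies outside the image")
  patch <- cropOriented(image, pUpper, d1, d2, len, w,
                        cfg$outputSize[1], cfg$outputSize[2])
  new("DiscROI", patch = patch, sourceRect = unname(corners),
      levelIndex = as.integer(levelIndex))
}

#' Train the reference herniation classifier
#'
#' Extracts the shared 572-dimensional descriptor from each ROI patch and
#' fits a two-class softmax head by seeded SGD. Both classes must be
#' present. Any model honoring the classifier interface (see
#' [classifyHerniation()]) may replace the result.
#'
#' @param rois list of [DiscROI-class] objects (or raw patch matrices).
#' @param labels factor/character with levels "normal" and "herniated".
#' @param seed RNG seed.
#' @param epochs,learningRate SGD hyperparameters of the head.
#' @return An [MlpModel-class] with classes normal/herniated.
#' @export
trainDiagnosisModel <- function(rois, labels, seed = 0L, epochs = 150L,
                                learningRate = 0.05) {
  labels <- factor(labels, levels = c("normal", "herniated"))
  if (any(is.na(labels)))
    stopf("spineDSS_validation_error", "labels must be 'normal' or 'herniated'")
  if (nlevels(droplevels(labels)) < 2)
    stopf("spineDSS_training_error", "need both classes to train the diagnosis model")
  X <- do.call(rbind, lapply(rois, function(r) {
    p <- if (is(r, "DiscROI")) roiPatch(r) else r
    buildFeatureVector(p)
  }))
  mlpTrain(X, labels, layerSizes = c(572L, 2L), learningRate = learningRate,
           momentum = 0.9, epochs = epochs, batchSize = 32L, seed = seed,
           featureMeta = list(blockSpans = featureBlockSpans(),
                              descriptor = "HPI+LBP+PHOG", task = "diagnosis"))
}

#' Classify a posterior disc ROI as herniated or normal
#'
#' @param roi a [DiscROI-class] (or raw patch matrix).
#' @param model a trained classifier from [trainDiagnosisModel()].
#' @return list(label = "herniated"/"normal", score = herniated-class
#'   probability in \[0, 1\]).
#' @export
classifyHerniation <- function(roi, model) {
  if (!isTrained(model))
    stopf("spineDSS_state_error", "diagnosis model has not been trained")
  p <- if (is(roi, "DiscROI")) roiPatch(roi) else roi
  probs <- mlpPredict(model, buildFeatureVector(p))[1, ]
  score <- unname(probs["herniated"])
  list(label = if (score > 0.5) "herniated" else "normal", score = score)
}
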