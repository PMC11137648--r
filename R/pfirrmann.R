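# Pfirrmann I-V grading: oriented disc crop -> 572-dimensional descriptor
# -> 572-300-150-5 MLP trained by stochastic gradient descent.

#' MLP configuration for Pfirrmann grading
#'
#' The architecture is fixed to 572 input neurons, hidden layers of 300 and
#' 150, and 5 output neurons (one per grade). SGD hyperparameters default to
#' ReLU activation, learning rate 0.01, momentum 0.9, 200 epochs, batch 32.
#'
#' @param learningRate,momentum,epochs,batchSize,seed SGD hyperparameters.
#' @return configuration list with the fixed \code{layerSizes}.
#' @export
pfirrmannMlpConfig <- function(learningRate = 0.01, momentum = 0.9,
                               epochs = 200L, batchSize = 32L, seed = 1L) {
  if (epochs < 1 || batchSize < 1)
    stopf("spineDSS_validation_error", "epochs and batchSize must be >= 1")
  list(layerSizes = c(572L, 300L, 150L, 5L), activation = "relu",
       learningRate = learningRate, momentum = momentum,
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       seed = as.integer(seed))
}

#' Oriented disc crop for grading
#'
#' Crops an oriented rectangle centered between two adjacent vertebra
#' centers: its width (and orientation) follow the line connecting the
#' centers, while the long axis runs perpendicular, spanning the disc
#' laterally over \code{lateralScale} times the inter-center distance. The
#' crop is resampled to a fixed patch (default 96 x 48: rows lateral,
#' columns along the inter-center line).
#'
#' @param image grayscale matrix.
#' @param pUpper,pLower adjacent vertebra centers (x, y), cranial then caudal.
#' @param outputSize c(lateral, axial) patch size; default c(96, 48).
#' @param lateralScale long-axis length as a multiple of the inter-center
#'   distance; default 1.5.
#' @return grayscale matrix of size \code{outputSize}.
#' @export
cropPfirrmannRoi <- function(image, pUpper, pLower, outputSize = c(96L, 48L),
                             lateralScale = 1.5) {
  d <- pLower - pUpper
  len <- sqrt(sum(d^2))
  if (len == 0)
    stopf("spineDSS_geometry_error", "vertebra centers coincide")
  aUnit <- d / len
  lUnit <- rot90vec(aUnit)
  ctr <- (pUpper + pLower) / 2
  L <- lateralScale * len
  origin <- ctr - lUnit * (L / 2) - aUnit * (len / 2)
  corners <- rbind(origin, origin + lUnit * L,
                   origin + lUnit * L + aUnit * len, origin + aUnit * len)
  if (all(corners[, 1] < 0) || all(corners[, 1] > ncol(image) - 1) ||
      all(corners[, 2] < 0) || all(corners[, 2] > nrow(image) - 1))
    stopf("spineDSS_geometry_error", "grading rectangle lies outside the image")
  cropOriented(image, origin, lUnit, aUnit, L, len, outputSize[1], outputSize[2])
}

#' Train the Pfirrmann grading MLP
#'
#' Trains the fixed 572-300-150-5 softmax MLP on labeled descriptors by
#' seeded mini-batch SGD; per-dimension standardization statistics are
#' fitted on the training data and stored in the model. All five grades
#' must be present.
#'
#' @param features n x 572 matrix of [buildFeatureVector()] descriptors (or
#'   a list of them).
#' @param grades integer grades in 1..5, one per row.
#' @param cfg a [pfirrmannMlpConfig()].
#' @return An [MlpModel-class] with classes "1".."5".
#' @export
trainPfirrmann <- function(features, grades, cfg = pfirrmannMlpConfig()) {
  if (is.list(features)) features <- do.call(rbind, features)
  grades <- as.integer(grades)
  if (!all(grades %in% 1:5))
    stopf("spineDSS_validation_error", "grades must be in 1..5")
  absent <- setdiff(1:5, unique(grades))
  if (length(absent))
    stopf("spineDSS_training_error", "missing Pfirrmann grade(s) in training data: %s",
          paste(absent, collapse = ", "))
  if (!identical(as.integer(cfg$layerSizes), c(572L, 300L, 150L, 5L)))
    stopf("spineDSS_validation_error", "layerSizes are fixed to 572-300-150-5")
  mlpTrain(features, factor(grades, levels = 1:5), cfg$layerSizes,
           learningRate = cfg$learningRate, momentum = cfg$momentum,
           epochs = cfg$epochs, batchSize = cfg$batchSize, seed = cfg$seed,
           featureMeta = list(blockSpans = featureBlockSpans(),
                              descriptor = "HPI+LBP+PHOG"))
}

#' Predict a Pfirrmann grade
#'
#' @param model a trained [MlpModel-class] from [trainPfirrmann()].
#' @param fv a 572-dimensional descriptor (or an n x 572 matrix).
#' @return For a single descriptor, list(grade, probabilities); grade is the
#'   argmax with ties resolved to the lowest grade. For a matrix, an integer
#'   vector of grades with the probability matrix as attribute.
#' @export
predictPfirrmann <- function(model, fv) {
  P <- mlpPredict(model, fv)
  g <- as.integer(model@classes[apply(P, 1, which.max)])
  if (nrow(P) == 1) return(list(grade = g, probabilities = P[1, ]))
  attr(g, "probabilities") <- P
  g
}

#' Roman-numeral rendering of Pfirrmann grades
#'
#' @param grade integer grades in 1..5.
#' @return character vector "I".."V".
#' @export
pfirrmannRoman <- function(grade) as.character(utils::as.roman(grade))
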