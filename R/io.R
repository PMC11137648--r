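# Readers/writers, annotation schema, dataset manifest arithmetic,
# configuration and augmentation policies.

#' Package configuration defaults
#'
#' @return nested list of module defaults; [readConfig()] layers a YAML file
#'   over these.
#' @export
defaultConfig <- function() {
  list(pixelSpacingMm = 0.2646,
       constraints = list(lambda1 = 0.6, lambda2 = 1.25,
                          theta1Deg = 140, theta2Deg = 180, maxRepairIters = 5),
       roi = list(stripWidthPx = 44, outputSize = c(64, 44)),
       augmentation = list(maxRotationDeg = 10, noiseSigmaRange = c(0, 5),
                           contrastRange = c(0.9, 1.1)),
       mlp = list(learningRate = 0.01, momentum = 0.9, epochs = 200, batchSize = 32))
}

#' Read a layered YAML configuration
#'
#' @param path YAML file; missing keys fall back to [defaultConfig()].
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Read a grayscale image
#'
#' Reads an 8/16-bit grayscale PNG as a 2-D matrix on the 8-bit scale
#' \[0, 255\] with the pixel spacing attached as attribute
#' \code{pixelSpacingMm}. Multi-channel files are averaged to one channel.
#' PNG carries no spacing metadata, so the spacing comes from the argument
#' (falling back to the configuration default of 0.2646 mm).
#'
#' @param path PNG file.
#' @param pixelSpacingMm spacing override; default NULL (use
#'   \code{defaultSpacing}).
#' @param defaultSpacing fallback spacing in mm; default 0.2646.
#' @return grayscale matrix with attribute \code{pixelSpacingMm}.
#' @export
readImageGray <- function(path, pixelSpacingMm = NULL, defaultSpacing = 0.2646) {
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stopf("spineDSS_io_error", "unsupported image format: %s (PNG only)", basename(path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  img <- a * 255
  attr(img, "pixelSpacingMm") <- if (is.null(pixelSpacingMm)) defaultSpacing else pixelSpacingMm
  img
}

#' @describeIn readImageGray write a matrix (8-bit scale) as grayscale PNG
#' @param img grayscale matrix on the 8-bit scale.
#' @export
writeImageGray <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Write a mask as a 0/255 PNG
#' @param mask 0/1 matrix or [HerniationMask-class].
#' @param path output file.
#' @export
writeMaskPng <- function(mask, path) {
  m <- if (is(mask, "HerniationMask")) maskMatrix(mask) else mask
  writeImageGray((m != 0) * 255, path)
}

annotationRequired <- list(
  points = c("points", "pixel_spacing_mm"),
  markers = c("markers", "pixel_spacing_mm"),
  labels = c("labels"))

#' Write an annotation file
#'
#' Annotations are JSON documents with a \code{schema_version}, a
#' \code{kind} ("points", "markers" or "labels"), the payload fields the
#' owning module defines, and any extra fields, which round-trip untouched.
#' Coordinates are 0-based pixels (x = column, y = row).
#'
#' @param x annotation list.
#' @param path output JSON file.
#' @export
writeAnnotation <- function(x, path) {
  if (is.null(x$schema_version)) x$schema_version <- "1.0"
  # compact canonical form so write-read-write is byte-stable
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @describeIn writeAnnotation read and schema-validate an annotation file
#' @param kind expected annotation kind; NULL accepts any.
#' @export
readAnnotation <- function(path, kind = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  k <- if (is.null(kind)) x$kind else kind
  if (!is.null(k) && k %in% names(annotationRequired)) {
    missing <- setdiff(annotationRequired[[k]], names(x))
    if (length(missing))
      stopf("spineDSS_schema_error", "annotation %s is missing field(s): %s",
            basename(path), paste(missing, collapse = ", "))
  }
  x
}

#' Marker annotation to MsuMarkerSet
#'
#' Converts the \code{markers} payload (named points D, Q, FsL, FsR, FiL,
#' FiR, M) of a marker annotation into an [MsuMarkerSet-class].
#'
#' @param ann annotation list from [readAnnotation()].
#' @export
markersFromAnnotation <- function(ann) {
  m <- ann$markers
  need <- c("D", "Q", "FsL", "FsR", "FiL", "FiR", "M")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stopf("spineDSS_schema_error", "marker annotation missing point(s): %s",
          paste(missing, collapse = ", "))
  msuMarkerSet(unlist(m$D), unlist(m$Q), unlist(m$FsL), unlist(m$FsR),
               unlist(m$FiL), unlist(m$FiR), unlist(m$M))
}

#' Study manifest
#'
#' @param nPatients,slicesPerPatient,discsPerPatient study dimensions.
#' @param trainPatients,testPatients patient split; must partition
#'   \code{nPatients}.
#' @return validated manifest list. Defaults mirror a 217-patient study with
#'   3 mid-sagittal slices and 5 lumbar discs per patient split 184/33.
#' @export
studyManifest <- function(nPatients = 217L, slicesPerPatient = 3L,
                          discsPerPatient = 5L, trainPatients = 184L,
                          testPatients = 33L) {
  if (trainPatients + testPatients != nPatients)
    stopf("spineDSS_validation_error",
          "train (%d) + test (%d) patients must partition %d",
          trainPatients, testPatients, nPatients)
  if (min(nPatients, slicesPerPatient, discsPerPatient) < 1)
    stopf("spineDSS_validation_error", "manifest dimensions must be positive")
  list(nPatients = as.integer(nPatients),
       slicesPerPatient = as.integer(slicesPerPatient),
       discsPerPatient = as.integer(discsPerPatient),
       trainPatients = as.integer(trainPatients),
       testPatients = as.integer(testPatients))
}

#' Disc-image count of a manifest subset
#'
#' patients x slices x discs for the chosen subset.
#'
#' @param m a [studyManifest()].
#' @param subset "all", "train" or "test".
#' @examples
#' discImageCount(studyManifest(), "all")  # 3255
#' @export
discImageCount <- function(m, subset = c("all", "train", "test")) {
  subset <- match.arg(subset)
  p <- switch(subset, all = m$nPatients, train = m$trainPatients,
              test = m$testPatients)
  p * m$slicesPerPatient * m$discsPerPatient
}

#' Seeded image augmentation
#'
#' The localization policy draws minor rotations, flips, a small amount of
#' Gaussian noise and slight contrast adjustment; the classification policy
#' is limited to minor rotations and flips so the diagnostic intensity
#' features are preserved. The drawn parameters are attached as attribute
#' \code{augParams}.
#'
#' @param image grayscale matrix (8-bit scale).
#' @param policy "localization" or "classification".
#' @param seed RNG seed.
#' @param maxRotationDeg rotation range is +/- this; default 10.
#' @param noiseSigmaRange,contrastRange localization-policy ranges.
#' @return augmented matrix with attribute \code{augParams}.
#' @export
augmentImage <- function(image, policy = c("localization", "classification"),
                         seed = NULL, maxRotationDeg = 10,
                         noiseSigmaRange = c(0, 5), contrastRange = c(0.9, 1.1)) {
  policy <- match.arg(policy)
  withSeed(seed, {
    params <- list(policy = policy,
                   rotationDeg = stats::runif(1, -maxRotationDeg, maxRotationDeg),
                   flipH = stats::runif(1) < 0.5,
                   flipV = stats::runif(1) < 0.5)
    out <- rotateImage(image, params$rotationDeg)
    if (params$flipH) out <- out[, ncol(out):1]
    if (params$flipV) out <- out[nrow(out):1, ]
    if (policy == "localization") {
      params$contrastGain <- stats::runif(1, contrastRange[1], contrastRange[2])
      params$noiseSigma <- stats::runif(1, noiseSigmaRange[1], noiseSigmaRange[2])
      out <- out * params$contrastGain
      if (params$noiseSigma > 0)
        out <- out + stats::rnorm(length(out), 0, params$noiseSigma)
      out <- clip255(out)
    }
    attr(out, "augParams") <- params
    out
  })
}
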