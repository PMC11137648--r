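# Procedural spine phantoms with exact analytic ground truth.
#
# Geometry is deliberately simple (ellipses, rounded rectangles, smooth
# arcs): the point of the generator is not realism but exact, seeded ground
# truth against which the localization, diagnosis, MSU and grading modules
# can be validated in a closed loop.

#' Phantom generator configuration
#'
#' @param imageSize pixels per side of the square raster (>= 128); default 512.
#' @param pixelSpacingMm mm per pixel; default 0.2646.
#' @param nVertebrae number of vertebral bodies on sagittal phantoms (>= 3).
#' @param noiseSigma std of the additive Gaussian intensity noise (8-bit
#'   scale) applied before clipping to \[0, 255\]; default 8.
#' @param lordosisDeg arc curvature (degrees subtended) of the vertebral
#'   chain; default 15.
#' @param seed integer RNG seed; together with the other fields it fully
#'   determines every output byte.
#' @return A validated configuration list.
#' @export
phantomConfig <- function(imageSize = 512L, pixelSpacingMm = 0.2646,
                          nVertebrae = 6L, noiseSigma = 8, lordosisDeg = 15,
                          seed = 1L) {
  cfg <- list(imageSize = as.integer(imageSize),
              pixelSpacingMm = pixelSpacingMm,
              nVertebrae = as.integer(nVertebrae),
              noiseSigma = noiseSigma, lordosisDeg = lordosisDeg,
              seed = as.integer(seed))
  if (cfg$imageSize < 128)
    stopf("spineDSS_validation_error", "imageSize must be >= 128 (got %d)", cfg$imageSize)
  if (!is.finite(cfg$pixelSpacingMm) || cfg$pixelSpacingMm <= 0)
    stopf("spineDSS_validation_error", "pixelSpacingMm must be positive")
  if (cfg$nVertebrae < 3)
    stopf("spineDSS_validation_error", "nVertebrae must be >= 3 (got %d)", cfg$nVertebrae)
  if (cfg$noiseSigma < 0)
    stopf("spineDSS_validation_error", "noiseSigma must be nonnegative")
  class(cfg) <- "PhantomConfig"
  cfg
}

#' Per-disc ground-truth specification
#'
#' @param pfirrmann integer vector of Pfirrmann grades in 1..5, one per disc.
#' @param herniated logical vector, one per disc.
#' @param msuSize,msuZone optional planted MSU labels (only meaningful for
#'   herniated discs); NA otherwise.
#' @return data.frame with columns level, pfirrmann, herniated, msuSize, msuZone.
#' @export
discSpecs <- function(pfirrmann, herniated = rep(FALSE, length(pfirrmann)),
                      msuSize = rep(NA_integer_, length(pfirrmann)),
                      msuZone = rep(NA_character_, length(pfirrmann))) {
  if (length(herniated) != length(pfirrmann))
    stopf("spineDSS_validation_error", "herniated and pfirrmann lengths differ")
  if (!all(pfirrmann %in% 1:5))
    stopf("spineDSS_validation_error", "pfirrmann grades must be in 1..5")
  if (any(!is.na(msuSize) & !herniated) || any(!is.na(msuZone) & !herniated))
    stopf("spineDSS_validation_error", "MSU fields are only allowed on herniated discs")
  data.frame(level = seq_along(pfirrmann),
             pfirrmann = as.integer(pfirrmann),
             herniated = as.logical(herniated),
             msuSize = as.integer(msuSize),
             msuZone = as.character(msuZone),
             stringsAsFactors = FALSE)
}

# Grade -> appearance mapping (8-bit scale). Encodes the Pfirrmann criteria
# as separable classes: T2 signal drops with grade, nucleus/annulus contrast
# vanishes, and grade-5 discs collapse in height.
gradeBaseIntensity <- function(g) 230 - 35 * (g - 1)
gradeContrast <- function(g) 1 - (g - 1) / 4
gradeHeightFactor <- function(g) ifelse(g == 5, 0.6, 1.0)

# Internal sagittal layout shared by generator and tests. All lengths scale
# with imageSize relative to the 512 reference frame.
sagittalLayout <- function(config) {
  S <- config$imageSize
  sc <- S / 512
  n <- config$nVertebrae
  y0 <- 60 * sc; y1 <- S - 60 * sc
  ys <- seq(y0, y1, length.out = n)
  span <- y1 - y0
  ymid <- (y0 + y1) / 2
  sag <- span * (config$lordosisDeg * pi / 180) / 8
  xs <- S / 2 + sag * (1 - (2 * (ys - ymid) / span)^2) - sag / 2
  list(centers = cbind(x = xs, y = ys), scale = sc,
       vertHalfWidth = 45 * sc, vertHalfHeight = 24 * sc, cornerRadius = 10 * sc,
       discHalfWidth = 30 * sc, discHalfHeight = 12 * sc,
       protLen = 10 * sc, protHalfHeight = 7 * sc,
       background = 28, vertebraValue = 185)
}

#' Generate a sagittal lumbar phantom
#'
#' Renders \code{nVertebrae} bright rounded-rectangle vertebral bodies along
#' a lordotic arc with an elliptical intervertebral disc between each pair.
#' Disc appearance follows the grade mapping: mean intensity
#' \code{230 - 35*(grade-1)}, nucleus/annulus contrast \code{1 - (grade-1)/4},
#' height factor 0.6 at grade 5. Herniated discs carry a posterior
#' (dorsal, +x) protrusion beyond the disc margin. Seeded Gaussian noise is
#' added last and the raster clipped to \[0, 255\].
#'
#' @param config a [phantomConfig()].
#' @param specs a [discSpecs()] data.frame with \code{nVertebrae - 1} rows.
#' @return A [SagittalPhantom-class] with exact ground truth.
#' @examples
#' ph <- generateSagittal(phantomConfig(seed = 7),
#'                        discSpecs(c(1, 2, 3, 4, 5)))
#' ph
#' @export
generateSagittal <- function(config, specs) {
  if (!inherits(config, "PhantomConfig"))
    config <- do.call(phantomConfig, config)
  if (nrow(specs) != config$nVertebrae - 1)
    stopf("spineDSS_validation_error",
          "need %d disc specs for %d vertebrae (got %d)",
          config$nVertebrae - 1, config$nVertebrae, nrow(specs))
  lay <- sagittalLayout(config)
  S <- config$imageSize
  g <- pixelGrids(S, S)
  img <- matrix(lay$background, S, S)

  # vertebral bodies: rounded rectangles centered on the arc
  for (k in seq_len(config$nVertebrae)) {
    dx <- abs(g$x - lay$centers[k, 1]); dy <- abs(g$y - lay$centers[k, 2])
    inRect <- dx <= lay$vertHalfWidth & dy <= lay$vertHalfHeight
    cx <- pmax(dx - (lay$vertHalfWidth - lay$cornerRadius), 0)
    cy <- pmax(dy - (lay$vertHalfHeight - lay$cornerRadius), 0)
    inRect <- inRect & (cx^2 + cy^2 <= lay$cornerRadius^2)
    img[inRect] <- lay$vertebraValue
  }

  regions <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    ctr <- (lay$centers[i, ] + lay$centers[i + 1, ]) / 2
    gr <- specs$pfirrmann[i]
    a <- lay$discHalfWidth
    b <- lay$discHalfHeight * gradeHeightFactor(gr)
    base <- gradeBaseIntensity(gr); con <- gradeContrast(gr)
    annulus <- base - 20 * con; nucleus <- base + 20 * con
    ell <- ((g$x - ctr[1]) / a)^2 + ((g$y - ctr[2]) / b)^2 <= 1
    img[ell] <- annulus
    nuc <- ((g$x - ctr[1]) / (0.6 * a))^2 + ((g$y - ctr[2]) / (0.6 * b))^2 <= 1
    img[nuc] <- nucleus
    prot <- matrix(FALSE, S, S)
    if (specs$herniated[i]) {
      # dorsal half-ellipse attached to the posterior disc margin
      pe <- ((g$x - (ctr[1] + a)) / lay$protLen)^2 +
        ((g$y - ctr[2]) / lay$protHalfHeight)^2 <= 1
      pe <- pe & g$x >= ctr[1] + a - 1e-9
      img[pe] <- annulus
      prot <- pe & !ell
    }
    regions[[i]] <- list(disc = which(ell), protrusion = which(prot))
  }

  img <- withSeed(config$seed, {
    if (config$noiseSigma > 0)
      img <- img + stats::rnorm(length(img), 0, config$noiseSigma)
    clip255(img)
  })

  new("SagittalPhantom", image = img, centers = lay$centers, dorsal = c(1, 0),
      discs = specs, regions = regions, config = unclass(config))
}

#' @describeIn generateSagittal per-disc pixel-region bookkeeping: list with
#'   integer raster indices \code{disc} and \code{protrusion} for each level.
#' @export
discRegions <- function(phantom) phantom@regions

# Internal axial layout (512 reference frame, scaled by imageSize).
# AP axis runs dorsally in +y; lateral unit is rot90(apUnit) = (-1, 0), so
# anatomically "left" markers (negative t) sit at larger x.
axialLayout <- function(config) {
  S <- config$imageSize
  sc <- S / 512
  cx <- S / 2; Dy <- 140 * sc
  list(scale = sc, D = c(cx, Dy), Q = c(cx, Dy + 115 * sc),
       M = c(cx, Dy + 40 * sc),
       FsL = c(cx + 52 * sc, Dy + 78 * sc), FsR = c(cx - 52 * sc, Dy + 78 * sc),
       FiL = c(cx + 58 * sc, Dy + 92 * sc), FiR = c(cx - 58 * sc, Dy + 92 * sc),
       bodyAxes = c(140, 48) * sc, discAxes = c(110, 38) * sc,
       canalCenterS = 78 * sc, canalAxes = c(65, 42) * sc,
       facetRadius = 4 * sc,
       background = 25, bodyValue = 120, discValue = 170, canalValue = 45,
       facetValue = 210, blobValue = 220)
}

# Apex placement bands in grid coordinates, >= 2 px inside every region
# boundary (margin scales with the raster so labels stay unambiguous).
axialApexBands <- function(lay) {
  sc <- lay$scale
  s0 <- 40 * sc; sIf <- 85 * sc; mid <- s0 + 0.5 * (sIf - s0)
  tB <- 55 * sc   # |t| of the intra-facet reference points
  m <- max(2, 2 * sc)
  list(s0 = s0, sIf = sIf, tB = tB, margin = m,
       sBand = list(`1` = c(s0 + 8 * sc, mid - m),
                    `2` = c(mid + m, sIf - m),
                    `3` = c(sIf + m, 108 * sc)),
       tBand = list(A = c(-(tB / 2 - m), tB / 2 - m),
                    B = rbind(c(-(tB - m), -(tB / 2 + m)), c(tB / 2 + m, tB - m)),
                    C = rbind(c(-(tB + 17 * sc), -(tB + m)), c(tB + m, tB + 17 * sc))))
}

#' Generate an axial lumbar phantom
#'
#' Renders an axial slice with vertebral body, intervertebral disc, spinal
#' canal, the six MSU marker points (facet apices drawn as small bright
#' blobs) and -- when \code{targetMsu} is given -- a bright half-elliptical
#' herniation blob attached to the posterior disc margin whose apex is
#' placed, by inverting the grid coordinate transform, strictly inside the
#' analytic MSU region for the requested (size, zone) with a margin of at
#' least 2 pixels from every region boundary.
#'
#' @param config a [phantomConfig()] (only imageSize, pixelSpacingMm,
#'   noiseSigma and seed are used).
#' @param targetMsu \code{list(size =, zone =)} with size in 1..3 and zone in
#'   A/B/C, or NULL for a herniation-free slice.
#' @param seed RNG seed for this slice; defaults to \code{config$seed}.
#' @return An [AxialPhantom-class] whose planted label is verified against
#'   [classifyMsu()] before returning.
#' @examples
#' ax <- generateAxial(phantomConfig(imageSize = 256), list(size = 2, zone = "B"))
#' phantomMsuTruth(ax)
#' @export
generateAxial <- function(config, targetMsu = NULL, seed = config$seed) {
  if (!inherits(config, "PhantomConfig"))
    config <- do.call(phantomConfig, config)
  if (!is.null(targetMsu)) {
    if (!targetMsu$size %in% 1:3 || !targetMsu$zone %in% c("A", "B", "C"))
      stopf("spineDSS_validation_error",
            "targetMsu must have size in 1..3 and zone in A/B/C")
  }
  lay <- axialLayout(config)
  S <- config$imageSize
  g <- pixelGrids(S, S)
  img <- matrix(lay$background, S, S)

  ell <- function(ctr, axes) ((g$x - ctr[1]) / axes[1])^2 + ((g$y - ctr[2]) / axes[2])^2 <= 1
  img[ell(lay$D, lay$bodyAxes)] <- lay$bodyValue
  img[ell(lay$D, lay$discAxes)] <- lay$discValue
  img[ell(c(lay$D[1], lay$D[2] + lay$canalCenterS), lay$canalAxes)] <- lay$canalValue
  for (f in list(lay$FsL, lay$FsR, lay$FiL, lay$FiR))
    img[ell(f, rep(lay$facetRadius, 2))] <- lay$facetValue

  markers <- msuMarkerSet(lay$D, lay$Q, lay$FsL, lay$FsR, lay$FiL, lay$FiR, lay$M)
  maskM <- matrix(0, S, S)
  truth <- list()

  out <- withSeed(seed, {
    if (!is.null(targetMsu)) {
      bands <- axialApexBands(lay)
      placed <- FALSE
      for (try in 1:20) {
        sb <- bands$sBand[[as.character(targetMsu$size)]]
        sA <- round(stats::runif(1, sb[1], sb[2]))
        tb <- bands$tBand[[targetMsu$zone]]
        if (is.matrix(tb)) tb <- tb[sample(nrow(tb), 1), ]
        tA <- round(stats::runif(1, tb[1], tb[2]))
        # rasterize: grid coords s = y - Dy, t = -(x - cx)
        sG <- g$y - lay$D[2]; tG <- -(g$x - lay$D[1])
        rs <- sA - bands$s0
        rt <- if (targetMsu$size == 1) stats::runif(1, 12, 16) * lay$scale
              else stats::runif(1, 14, 22) * lay$scale
        blob <- ((tG - tA) / rt)^2 + ((sG - bands$s0) / rs)^2 <= 1 & sG >= bands$s0
        cand <- matrix(as.numeric(blob), S, S)
        lab <- tryCatch(
          classifyMsu(markers, herniationMask(cand, config$pixelSpacingMm)),
          error = function(e) NULL)
        if (!is.null(lab) && lab$size == targetMsu$size && lab$zone == targetMsu$zone) {
          maskM <- cand
          img[blob] <- lay$blobValue
          truth <- list(size = as.integer(targetMsu$size), zone = targetMsu$zone)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("spineDSS_generation_error",
              "could not place a herniation apex for MSU %d-%s",
              targetMsu$size, targetMsu$zone)
    }
    if (config$noiseSigma > 0)
      img <- img + stats::rnorm(length(img), 0, config$noiseSigma)
    list(img = clip255(img), mask = maskM, truth = truth)
  })

  new("AxialPhantom", image = out$img, markers = markers,
      maskTruth = herniationMask(out$mask, config$pixelSpacingMm),
      msuTruth = out$truth, config = unclass(config))
}
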