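#' @import methods
NULL

#' Ordered vertebra landmark chain
#'
#' An ordered list of vertebral-body center points \eqn{P_1..P_n} on a
#' sagittal slice, cranial to caudal, in 0-based pixel coordinates
#' (x = column, y = row, y increasing caudally). The chain is the object of
#' the anatomical distance and angle constraints used to repair detector
#' output.
#'
#' @slot points numeric matrix, one row per point, columns x and y.
#' @slot pixelSpacingMm physical pixel size in mm (isotropic).
#' @export
setClass("PointChain",
         representation(points = "matrix", pixelSpacingMm = "numeric"),
         validity = function(object) {
           p <- object@points
           if (!is.numeric(p) || ncol(p) != 2) return("points must be an n x 2 numeric matrix")
           if (any(!is.finite(p))) return("points must be finite")
           if (length(object@pixelSpacingMm) != 1 || object@pixelSpacingMm <= 0)
             return("pixelSpacingMm must be a single positive number")
           TRUE
         })

#' Construct a PointChain
#'
#' @param points n x 2 numeric matrix (or list of length-2 points), columns
#'   x and y, ordered cranial to caudal.
#' @param pixelSpacingMm mm per pixel; default 0.2646.
#' @return A [PointChain-class] object.
#' @examples
#' pointChain(rbind(c(0, 0), c(3, 4), c(6, 8)))
#' @export
pointChain <- function(points, pixelSpacingMm = 0.2646) {
  if (is.list(points)) points <- do.call(rbind, points)
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  new("PointChain", points = points, pixelSpacingMm = pixelSpacingMm)
}

#' @describeIn pointChain coordinate matrix accessor
#' @param chain a PointChain
#' @export
chainPoints <- function(chain) chain@points

#' @describeIn pointChain pixel spacing accessor (mm per pixel)
#' @export
pixelSpacing <- function(chain) chain@pixelSpacingMm

#' @describeIn pointChain number of points
#' @export
nPoints <- function(chain) nrow(chain@points)

setMethod("show", "PointChain", function(object) {
  cat(sprintf("PointChain with %d points (%.4f mm/px)\n",
              nrow(object@points), object@pixelSpacingMm))
  print(utils::head(object@points, 3))
  if (nrow(object@points) > 3) cat("...\n")
})

#' Axial MSU marker points
#'
#' The six anatomical marker points of the MSU classification on an axial
#' slice -- intervertebral disc center, dorsal point of the spinal canal, and
#' the ventral apices of the left/right superior and inferior articular
#' processes -- plus the posterior disc margin point that anchors the size-1
#' band. Coordinates are 0-based pixels. "Left"/"right" refer to the two
#' sides of the anteroposterior (AP) axis through disc center and canal
#' dorsal point: left-labeled markers must have negative lateral coordinate
#' in the grid frame (see [buildGrid()]).
#'
#' @slot discCenter point D.
#' @slot canalDorsal point Q, dorsal-most point of the spinal canal.
#' @slot facetSupLeft,facetSupRight ventral apices, superior articular processes.
#' @slot facetInfLeft,facetInfRight ventral apices, inferior articular processes.
#' @slot posteriorMargin point M, posterior disc margin on the AP axis.
#' @export
setClass("MsuMarkerSet",
         representation(discCenter = "numeric", canalDorsal = "numeric",
                        facetSupLeft = "numeric", facetSupRight = "numeric",
                        facetInfLeft = "numeric", facetInfRight = "numeric",
                        posteriorMargin = "numeric"),
         validity = function(object) {
           pts <- list(object@discCenter, object@canalDorsal, object@facetSupLeft,
                       object@facetSupRight, object@facetInfLeft,
                       object@facetInfRight, object@posteriorMargin)
           if (!all(vapply(pts, isPoint, logical(1))))
             return("all markers must be finite length-2 numeric points")
           D <- object@discCenter; Q <- object@canalDorsal
           if (all(D == Q)) return("canalDorsal must differ from discCenter")
           u <- (Q - D) / sqrt(sum((Q - D)^2))
           v <- rot90vec(u)
           tc <- function(p) sum((p - D) * v)
           sc <- function(p) sum((p - D) * u)
           if (tc(object@facetSupLeft) >= 0 || tc(object@facetInfLeft) >= 0)
             return("left facet markers must lie at negative lateral coordinate")
           if (tc(object@facetSupRight) <= 0 || tc(object@facetInfRight) <= 0)
             return("right facet markers must lie at positive lateral coordinate")
           sM <- sc(object@posteriorMargin); sQ <- sc(Q)
           if (sM <= 0 || sM >= sQ)
             return("posteriorMargin must lie strictly between disc center and canal dorsal point on the AP axis")
           TRUE
         })

#' Construct an MsuMarkerSet
#'
#' @param discCenter,canalDorsal,facetSupLeft,facetSupRight,facetInfLeft,facetInfRight,posteriorMargin
#'   length-2 numeric points (x, y) in 0-based pixel coordinates.
#' @return An [MsuMarkerSet-class] object.
#' @export
msuMarkerSet <- function(discCenter, canalDorsal, facetSupLeft, facetSupRight,
                         facetInfLeft, facetInfRight, posteriorMargin) {
  new("MsuMarkerSet",
      discCenter = as.numeric(discCenter), canalDorsal = as.numeric(canalDorsal),
      facetSupLeft = as.numeric(facetSupLeft), facetSupRight = as.numeric(facetSupRight),
      facetInfLeft = as.numeric(facetInfLeft), facetInfRight = as.numeric(facetInfRight),
      posteriorMargin = as.numeric(posteriorMargin))
}

setMethod("show", "MsuMarkerSet", function(object) {
  cat("MsuMarkerSet\n")
  cat(sprintf("  D  = (%.1f, %.1f)   Q = (%.1f, %.1f)   M = (%.1f, %.1f)\n",
              object@discCenter[1], object@discCenter[2],
              object@canalDorsal[1], object@canalDorsal[2],
              object@posteriorMargin[1], object@posteriorMargin[2]))
  cat(sprintf("  facets sup (L/R): (%.1f, %.1f) / (%.1f, %.1f)\n",
              object@facetSupLeft[1], object@facetSupLeft[2],
              object@facetSupRight[1], object@facetSupRight[2]))
  cat(sprintf("  facets inf (L/R): (%.1f, %.1f) / (%.1f, %.1f)\n",
              object@facetInfLeft[1], object@facetInfLeft[2],
              object@facetInfRight[1], object@facetInfRight[2]))
})

#' MSU classification grid
#'
#' The axial coordinate frame and region boundaries derived from an
#' [MsuMarkerSet-class] by [buildGrid()]. AP coordinate s increases dorsally
#' from the disc center D; lateral coordinate t is measured across the AP
#' axis (left negative).
#'
#' @slot origin disc center D.
#' @slot apUnit unit vector of the AP axis (D towards Q).
#' @slot latUnit apUnit rotated +90 degrees.
#' @slot s0 AP coordinate of the posterior disc margin M (size-1 origin).
#' @slot sIf AP coordinate of the intra-facet line on the AP axis (size-3 boundary).
#' @slot tLeft,tRight lateral coordinates of the per-side intra-facet
#'   reference points (zone B/C boundaries); half of each is the zone A/B
#'   boundary.
#' @export
setClass("MsuGrid",
         representation(origin = "numeric", apUnit = "numeric", latUnit = "numeric",
                        s0 = "numeric", sIf = "numeric",
                        tLeft = "numeric", tRight = "numeric"),
         validity = function(object) {
           if (object@sIf <= object@s0) return("sIf must exceed s0")
           if (!(object@tLeft < 0 && object@tRight > 0))
             return("tLeft must be negative and tRight positive")
           TRUE
         })

setMethod("show", "MsuGrid", function(object) {
  cat(sprintf("MsuGrid: s0 = %.2f, sIf = %.2f, tLeft = %.2f, tRight = %.2f\n",
              object@s0, object@sIf, object@tLeft, object@tRight))
})

#' Binary herniation mask
#'
#' A binary raster aligned with its source axial image; foreground marks the
#' herniated area. The dorsal-most foreground pixel (the apex) drives MSU
#' assignment.
#'
#' @slot mask 0/1 numeric matrix with the shape of the source image.
#' @slot pixelSpacingMm mm per pixel.
#' @export
setClass("HerniationMask",
         representation(mask = "matrix", pixelSpacingMm = "numeric"),
         validity = function(object) {
           if (!all(object@mask %in% c(0, 1))) return("mask values must be 0/1")
           if (object@pixelSpacingMm <= 0) return("pixelSpacingMm must be positive")
           TRUE
         })

#' Construct a HerniationMask
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param pixelSpacingMm mm per pixel; default 0.2646.
#' @export
herniationMask <- function(mask, pixelSpacingMm = 0.2646) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  new("HerniationMask", mask = m, pixelSpacingMm = pixelSpacingMm)
}

#' @describeIn herniationMask the 0/1 matrix
#' @param x a HerniationMask
#' @export
maskMatrix <- function(x) x@mask

setMethod("show", "HerniationMask", function(object) {
  cat(sprintf("HerniationMask %dx%d, %d foreground px\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

#' Synthetic sagittal phantom
#'
#' A procedurally generated sagittal lumbar slice with exact ground truth:
#' the rendered raster, the true vertebral-body centers, the dorsal
#' direction, the per-disc specification (Pfirrmann grade, herniation), and
#' per-disc pixel index sets for the disc body and any posterior protrusion.
#'
#' @slot image 8-bit-range grayscale matrix.
#' @slot centers n x 2 matrix of true vertebra centers (x, y), cranial to caudal.
#' @slot dorsal unit 2-vector pointing dorsally (posterior).
#' @slot discs data.frame of disc ground truth (level, pfirrmann, herniated).
#' @slot regions per-disc list: integer pixel indices of disc and protrusion.
#' @slot config the generating [phantomConfig()] list.
#' @export
setClass("SagittalPhantom",
         representation(image = "matrix", centers = "matrix", dorsal = "numeric",
                        discs = "data.frame", regions = "list", config = "list"),
         validity = function(object) {
           n <- nrow(object@centers)
           if (nrow(object@discs) != n - 1) return("need one disc per adjacent vertebra pair")
           S <- dim(object@image)
           if (any(object@centers[, 1] < 0 | object@centers[, 1] > S[2] - 1 |
                   object@centers[, 2] < 0 | object@centers[, 2] > S[1] - 1))
             return("all vertebra centers must lie inside the raster")
           TRUE
         })

setMethod("show", "SagittalPhantom", function(object) {
  cat(sprintf("SagittalPhantom %dx%d: %d vertebrae, %d discs (grades %s; %d herniated)\n",
              nrow(object@image), ncol(object@image), nrow(object@centers),
              nrow(object@discs), paste(object@discs$pfirrmann, collapse = ","),
              sum(object@discs$herniated)))
})

#' Synthetic axial phantom
#'
#' A procedurally generated axial slice: raster, the six MSU marker points
#' (plus posterior disc margin), the ground-truth herniation mask, and -- when
#' a herniation was requested -- the planted MSU (size, zone) label.
#'
#' @slot image grayscale matrix.
#' @slot markers [MsuMarkerSet-class].
#' @slot maskTruth [HerniationMask-class] (empty when no herniation requested).
#' @slot msuTruth list(size, zone) or empty list.
#' @slot config the generating config list.
#' @export
setClass("AxialPhantom",
         representation(image = "matrix", markers = "MsuMarkerSet",
                        maskTruth = "HerniationMask", msuTruth = "list",
                        config = "list"),
         validity = function(object) {
           has_mask <- sum(object@maskTruth@mask) > 0
           has_truth <- length(object@msuTruth) > 0
           if (has_mask != has_truth)
             return("maskTruth must be nonempty exactly when an MSU label was planted")
           TRUE
         })

setMethod("show", "AxialPhantom", function(object) {
  if (length(object@msuTruth) > 0) {
    cat(sprintf("AxialPhantom %dx%d with herniation (MSU %d-%s, %d px)\n",
                nrow(object@image), ncol(object@image),
                object@msuTruth$size, object@msuTruth$zone,
                sum(object@maskTruth@mask)))
  } else {
    cat(sprintf("AxialPhantom %dx%d, no herniation\n",
                nrow(object@image), ncol(object@image)))
  }
})

#' @describeIn generateSagittal image accessor (works for both phantom kinds)
#' @param phantom a phantom object
#' @export
phantomImage <- function(phantom) phantom@image

#' @describeIn generateSagittal true vertebra centers of a sagittal phantom
#' @export
vertebraCenters <- function(phantom) phantom@centers

#' @describeIn generateSagittal per-disc ground-truth data.frame
#' @export
discTruth <- function(phantom) phantom@discs

#' @describeIn generateAxial marker accessor
#' @export
phantomMarkers <- function(phantom) phantom@markers

#' @describeIn generateAxial ground-truth mask accessor
#' @export
phantomMaskTruth <- function(phantom) phantom@maskTruth

#' @describeIn generateAxial planted MSU label (list(size, zone) or empty list)
#' @export
phantomMsuTruth <- function(phantom) phantom@msuTruth

#' Oriented posterior disc region of interest
#'
#' The resampled patch and source-geometry of an oriented rectangle cropped
#' from a sagittal slice by [cropDiscRoi()].
#'
#' @slot patch resampled grayscale matrix (rows along the inter-vertebra
#'   segment, columns along the dorsal direction).
#' @slot sourceRect 4 x 2 matrix of rectangle corners in source pixel
#'   coordinates, in order upper, lower, lower+dorsal, upper+dorsal.
#' @slot levelIndex 1-based disc level.
#' @export
setClass("DiscROI",
         representation(patch = "matrix", sourceRect = "matrix",
                        levelIndex = "integer"),
         validity = function(object) {
           r <- object@sourceRect
           if (nrow(r) != 4 || ncol(r) != 2) return("sourceRect must be 4 x 2")
           d1 <- r[2, ] - r[1, ]; d2 <- r[3, ] - r[4, ]
           d3 <- r[4, ] - r[1, ]; d4 <- r[3, ] - r[2, ]
           if (max(abs(d1 - d2)) > 1e-6 || max(abs(d3 - d4)) > 1e-6)
             return("sourceRect corners must form a parallelogram")
           if (abs(sum(d1 * d3)) > 1e-6) return("sourceRect sides must be orthogonal")
           TRUE
         })

#' @describeIn cropDiscRoi patch accessor
#' @param roi a DiscROI
#' @export
roiPatch <- function(roi) roi@patch

#' @describeIn cropDiscRoi source rectangle corners (4 x 2)
#' @export
roiSourceRect <- function(roi) roi@sourceRect

setMethod("show", "DiscROI", function(object) {
  cat(sprintf("DiscROI level %d, patch %dx%d\n", object@levelIndex,
              nrow(object@patch), ncol(object@patch)))
})

#' Trained multi-layer perceptron model
#'
#' Weights, biases, per-dimension standardization statistics and training
#' configuration of a softmax MLP trained by seeded stochastic gradient
#' descent. Used both for the 572-300-150-5 Pfirrmann grader and the
#' two-class herniation head.
#'
#' @slot weights,biases per-layer parameter lists.
#' @slot norm list(mean, sd) fitted on training features.
#' @slot classes class labels in output order.
#' @slot config the training configuration list.
#' @slot lossHistory mean cross-entropy per epoch.
#' @slot featureMeta descriptor metadata (block split etc.).
#' @export
setClass("MlpModel",
         representation(weights = "list", biases = "list", norm = "list",
                        classes = "character", config = "list",
                        lossHistory = "numeric", featureMeta = "list"))

#' @describeIn trainPfirrmann TRUE when the model holds trained weights
#' @param model an MlpModel
#' @export
isTrained <- function(model) {
  is(model, "MlpModel") && length(model@weights) > 0
}

setMethod("show", "MlpModel", function(object) {
  sizes <- object@config$layerSizes
  cat(sprintf("MlpModel %s, classes: %s, %d epochs (final loss %.4f)\n",
              paste(sizes, collapse = "-"),
              paste(object@classes, collapse = "/"),
              length(object@lossHistory),
              utils::tail(object@lossHistory, 1)))
})
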