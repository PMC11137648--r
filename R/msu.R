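# MSU classification geometry on axial slices.
#
# The MSU scheme divides the spinal canal with lines derived from six
# anatomical marker points; the herniation's size (1/2/3, posterior extent)
# and zone (A/B/C, central to lateral) follow from the region in which the
# apex of the herniated area lies.

#' Build the MSU classification grid from axial markers
#'
#' The anteroposterior (AP) axis runs from the disc center D towards the
#' dorsal canal point Q; its unit vector and the +90-degree rotated lateral
#' unit define grid coordinates \eqn{s} (AP, dorsal positive) and \eqn{t}
#' (lateral, left negative). Per-side intra-facet reference points are the
#' midpoints of the superior and inferior facet apices on each side; the
#' intra-facet line connects them and its intersection with the AP axis
#' gives the size-3 boundary \code{sIf}. The posterior disc margin M gives
#' the size-1 origin \code{s0}; the size-1/2 boundary lies halfway between.
#' Lateral zone boundaries sit at half (\code{A/B}) and at the full
#' (\code{B/C}) lateral coordinates of the intra-facet reference points.
#'
#' @param markers an [MsuMarkerSet-class].
#' @return An [MsuGrid-class].
#' @export
buildGrid <- function(markers) {
  validObject(markers)
  D <- markers@discCenter
  u <- unitVec(markers@canalDorsal - D)
  v <- rot90vec(u)
  sc <- function(p) sum((p - D) * u)
  tc <- function(p) sum((p - D) * v)
  FL <- (markers@facetSupLeft + markers@facetInfLeft) / 2
  FR <- (markers@facetSupRight + markers@facetInfRight) / 2
  tL <- tc(FL); tR <- tc(FR)
  if (abs(tR - tL) < 1e-9)
    stopf("spineDSS_geometry_error", "intra-facet line is parallel to the AP axis")
  # intersection of segment FL-FR with the AP axis (t = 0)
  w <- (0 - tL) / (tR - tL)
  sIf <- sc(FL) + w * (sc(FR) - sc(FL))
  s0 <- sc(markers@posteriorMargin)
  if (sIf <= s0)
    stopf("spineDSS_geometry_error",
          "intra-facet line (s = %.2f) must lie dorsal of the disc margin (s = %.2f)",
          sIf, s0)
  new("MsuGrid", origin = D, apUnit = u, latUnit = v,
      s0 = s0, sIf = sIf, tLeft = tL, tRight = tR)
}

#' Grid coordinates of points
#'
#' @param grid an [MsuGrid-class].
#' @param pts n x 2 matrix (or length-2 point) of pixel coordinates.
#' @return n x 2 matrix with columns s (AP) and t (lateral).
#' @export
gridCoords <- function(grid, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  dx <- pts[, 1] - grid@origin[1]; dy <- pts[, 2] - grid@origin[2]
  cbind(s = dx * grid@apUnit[1] + dy * grid@apUnit[2],
        t = dx * grid@latUnit[1] + dy * grid@latUnit[2])
}

#' Reference threshold segmenter for the herniated area
#'
#' A classical implementation of the pluggable segmenter interface:
#' intensity thresholding restricted to the band dorsal of the posterior
#' disc margin (grid coordinate \code{s > s0}), largest connected component,
#' hole filling. Any learned segmenter with the same signature may replace it.
#'
#' @param threshold grayscale threshold; default 140.
#' @return A segmenter closure \code{function(image, markers) -> 0/1 matrix}.
#' @export
thresholdSegmenter <- function(threshold = 140) {
  function(image, markers) {
    grid <- buildGrid(markers)
    g <- pixelGrids(nrow(image), ncol(image))
    s <- (g$x - grid@origin[1]) * grid@apUnit[1] +
      (g$y - grid@origin[2]) * grid@apUnit[2]
    cand <- image > threshold & s >= grid@s0
    if (!any(cand)) return(matrix(0, nrow(image), ncol(image)))
    lab <- EBImage::bwlabel(cand)
    tab <- tabulate(lab[lab > 0])
    keep <- lab == which.max(tab)
    filled <- EBImage::fillHull(matrix(as.numeric(keep), nrow(image), ncol(image)))
    matrix(as.numeric(filled > 0), nrow(image), ncol(image))
  }
}

#' Segmenter that returns a fixed mask
#'
#' Adapts a known mask (e.g., a manual annotation) to the segmenter
#' interface.
#'
#' @param mask 0/1 matrix or [HerniationMask-class].
#' @export
identitySegmenter <- function(mask) {
  m <- if (is(mask, "HerniationMask")) maskMatrix(mask) else mask
  function(image, markers) m
}

#' Segment the herniated area on an axial slice
#'
#' @param image grayscale matrix.
#' @param markers an [MsuMarkerSet-class].
#' @param segmenter a segmenter function; default [thresholdSegmenter()].
#' @param pixelSpacingMm spacing attached to the mask.
#' @return A [HerniationMask-class]. An empty result is legal (it raises a
#'   warning, not an error, since the upstream diagnosis may be wrong).
#' @export
segmentHerniation <- function(image, markers, segmenter = thresholdSegmenter(),
                              pixelSpacingMm = 0.2646) {
  if (!is.matrix(image))
    stopf("spineDSS_validation_error", "image must be a single-channel matrix")
  m <- segmenter(image, markers)
  if (sum(m) == 0)
    warnf("spineDSS_empty_segmentation", "segmenter produced an empty herniation mask")
  herniationMask(m, pixelSpacingMm)
}

#' Apex of the herniated area
#'
#' The mask pixel with maximal AP coordinate \eqn{s}; ties are broken by
#' minimal absolute lateral coordinate \eqn{|t|}, then by raster order
#' (column-major pixel index).
#'
#' @param mask a [HerniationMask-class] (nonempty).
#' @param grid an [MsuGrid-class].
#' @return list(point = c(x, y), s =, t =).
#' @export
findApex <- function(mask, grid) {
  m <- maskMatrix(mask)
  idx <- which(m != 0)
  if (length(idx) == 0)
    stopf("spineDSS_empty_mask", "cannot find the apex of an empty mask")
  yy <- (idx - 1) %% nrow(m)
  xx <- (idx - 1) %/% nrow(m)
  st <- gridCoords(grid, cbind(xx, yy))
  ord <- order(-st[, "s"], abs(st[, "t"]), idx)
  k <- ord[1]
  list(point = c(x = xx[k], y = yy[k]), s = st[k, "s"], t = st[k, "t"])
}

#' MSU size/zone classification from markers and mask
#'
#' With apex grid coordinates \eqn{(s_a, t_a)}: size 1 when
#' \eqn{s_a \le s_0 + (s_{if} - s_0)/2}, size 2 up to and including
#' \eqn{s_{if}}, size 3 strictly beyond. Zone A when \eqn{t_a} lies strictly
#' between half the lateral boundaries, C at or beyond the full boundaries,
#' B in between; lateral boundary ties assign the more lateral zone.
#'
#' @param markers an [MsuMarkerSet-class].
#' @param mask a nonempty [HerniationMask-class].
#' @return list(size, zone) with size in 1..3, zone in A/B/C.
#' @examples
#' ax <- generateAxial(phantomConfig(imageSize = 256), list(size = 3, zone = "C"))
#' classifyMsu(phantomMarkers(ax), phantomMaskTruth(ax))
#' @export
classifyMsu <- function(markers, mask) {
  grid <- buildGrid(markers)
  apex <- findApex(mask, grid)
  sA <- apex$s; tA <- apex$t
  size <- if (sA <= grid@s0 + 0.5 * (grid@sIf - grid@s0)) 1L
          else if (sA <= grid@sIf) 2L else 3L
  zone <- if (tA > 0.5 * grid@tLeft && tA < 0.5 * grid@tRight) "A"
          else if (tA > grid@tLeft && tA < grid@tRight) "B"
          else "C"
  list(size = size, zone = zone, apex = apex)
}

#' Rasterized MSU region map
#'
#' Paints every pixel of a raster with its (size, zone) region by evaluating
#' the grid coordinates pixel by pixel -- a brute-force companion to the
#' analytic [classifyMsu()] rule, useful for visualization and as an
#' independent cross-check. Region codes are \code{size * 10 + zone} with
#' zone A/B/C coded 1/2/3.
#'
#' @param grid an [MsuGrid-class].
#' @param dim c(nrow, ncol) of the raster to paint.
#' @return integer matrix of region codes.
#' @export
rasterizeMsuRegions <- function(grid, dim) {
  g <- pixelGrids(dim[1], dim[2])
  dx <- g$x - grid@origin[1]; dy <- g$y - grid@origin[2]
  s <- dx * grid@apUnit[1] + dy * grid@apUnit[2]
  t <- dx * grid@latUnit[1] + dy * grid@latUnit[2]
  half <- grid@s0 + (grid@sIf - grid@s0) / 2
  size <- matrix(3L, dim[1], dim[2])
  size[s <= grid@sIf] <- 2L
  size[s <= half] <- 1L
  zone <- matrix(3L, dim[1], dim[2])
  zone[t > grid@tLeft & t < grid@tRight] <- 2L
  zone[t > 0.5 * grid@tLeft & t < 0.5 * grid@tRight] <- 1L
  size * 10L + zone
}
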