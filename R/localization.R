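# Vertebral-body localization and anatomical constraint repair.
#
# The detector is a pluggable interface (any function image -> candidate
# boxes/points); the package ships a classical bright-blob reference
# detector. The substance of this module is the post-processing: consecutive
# landmark distances must keep a bounded ratio and the angle at each interior
# landmark must stay near straight, reflecting the limited mobility of the
# lumbar spine; points violating the constraints are replaced from their
# trusted neighbors.

#' Anatomical constraint configuration
#'
#' Bounds of the distance-ratio and angle constraints on a vertebral
#' landmark chain, with defaults \eqn{\lambda_1 = 0.6}, \eqn{\lambda_2 = 1.25},
#' \eqn{\theta_1 = 140^\circ}, \eqn{\theta_2 = 180^\circ}.
#'
#' @param lambda1,lambda2 lower/upper bound on the ratio of consecutive
#'   segment lengths \eqn{V_i / V_{i-1}} (strict); require
#'   \code{0 < lambda1 < 1 < lambda2}.
#' @param theta1Deg,theta2Deg angle bounds in degrees at each interior
#'   landmark; the test applied is \code{theta1Deg < angle <= theta2Deg}
#'   (the upper bound is inclusive because a perfectly straight chain --
#'   exactly 180 degrees -- is the anatomical ideal, not a violation).
#' @param maxRepairIters maximum repair sweeps; default 5.
#' @return A validated configuration list.
#' @export
constraintConfig <- function(lambda1 = 0.6, lambda2 = 1.25,
                             theta1Deg = 140, theta2Deg = 180,
                             maxRepairIters = 5L) {
  if (!(lambda1 > 0 && lambda1 < 1 && lambda2 > 1))
    stopf("spineDSS_validation_error", "need 0 < lambda1 < 1 < lambda2")
  if (!(theta1Deg > 0 && theta1Deg < theta2Deg && theta2Deg <= 180))
    stopf("spineDSS_validation_error", "need 0 < theta1Deg < theta2Deg <= 180")
  list(lambda1 = lambda1, lambda2 = lambda2,
       theta1Deg = theta1Deg, theta2Deg = theta2Deg,
       maxRepairIters = as.integer(maxRepairIters))
}

#' Reference bright-blob vertebra detector
#'
#' A classical detector for the pluggable detector interface: global
#' threshold, connected components, and an area filter that separates the
#' large bright vertebral bodies from the smaller discs. Tuned to the
#' phantom geometry at the 512-pixel scale; any function
#' \code{image -> list(boxes, scores, points)} may replace it.
#'
#' @param threshold grayscale threshold (8-bit scale); default 150.
#' @param minArea,maxArea component area band in pixels.
#' @return A detector closure.
#' @export
blobDetector <- function(threshold = 150, minArea = 2500, maxArea = 12000) {
  function(image) {
    lab <- EBImage::bwlabel(image > threshold)
    ids <- setdiff(sort(unique(as.vector(lab))), 0)
    pts <- NULL; boxes <- NULL
    for (id in ids) {
      idx <- which(lab == id)
      if (length(idx) < minArea || length(idx) > maxArea) next
      yy <- (idx - 1) %% nrow(image)
      xx <- (idx - 1) %/% nrow(image)
      pts <- rbind(pts, c(mean(xx), mean(yy)))
      boxes <- rbind(boxes, c(min(xx), min(yy), max(xx), max(yy)))
    }
    if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
    if (is.null(boxes)) boxes <- matrix(numeric(0), 0, 4)
    list(boxes = boxes, scores = rep(1, nrow(pts)), points = pts)
  }
}

#' Detect vertebral bodies on a sagittal slice
#'
#' Runs a detector over a single-channel raster and returns candidate
#' vertebra centers sorted cranial to caudal (increasing y).
#'
#' @param image grayscale matrix.
#' @param detector a detector function; default [blobDetector()].
#' @param pixelSpacingMm spacing attached to the resulting chain.
#' @return list with \code{boxes}, \code{scores}, \code{points} and
#'   \code{chain} (a [PointChain-class]).
#' @export
detectVertebrae <- function(image, detector = blobDetector(),
                            pixelSpacingMm = 0.2646) {
  if (!is.matrix(image))
    stopf("spineDSS_validation_error", "image must be a single-channel matrix")
  res <- detector(image)
  if (nrow(res$points) < 3)
    stopf("spineDSS_chain_too_short",
          "detector produced %d candidate(s); need at least 3", nrow(res$points))
  ord <- order(res$points[, 2])
  res$points <- res$points[ord, , drop = FALSE]
  res$boxes <- res$boxes[ord, , drop = FALSE]
  res$scores <- res$scores[ord]
  res$chain <- pointChain(res$points, pixelSpacingMm)
  res
}

#' Segment length of a landmark chain
#'
#' The Euclidean distance \eqn{V_i} between \eqn{P_{i+1}} and \eqn{P_i}, in
#' pixels.
#'
#' @param chain a [PointChain-class].
#' @param i segment index, \code{1 <= i <= n - 1}.
#' @export
segmentLength <- function(chain, i) {
  p <- chainPoints(chain)
  if (i < 1 || i > nrow(p) - 1)
    stopf("spineDSS_validation_error", "segment index %d out of range 1..%d", i, nrow(p) - 1)
  sqrt(sum((p[i + 1, ] - p[i, ])^2))
}

#' Distance constraint at an interior landmark
#'
#' TRUE iff the strict double inequality
#' \eqn{\lambda_1 < V_i / V_{i-1} < \lambda_2} holds at vertex \eqn{P_i}.
#'
#' @param chain a [PointChain-class].
#' @param i interior index, \code{2 <= i <= n - 1}.
#' @param cfg a [constraintConfig()].
#' @export
distanceOk <- function(chain, i, cfg = constraintConfig()) {
  p <- chainPoints(chain)
  if (i < 2 || i > nrow(p) - 1)
    stopf("spineDSS_validation_error", "index %d out of range 2..%d", i, nrow(p) - 1)
  vPrev <- segmentLength(chain, i - 1)
  if (vPrev == 0)
    stopf("spineDSS_geometry_error", "zero-length segment preceding index %d", i)
  r <- segmentLength(chain, i) / vPrev
  r > cfg$lambda1 && r < cfg$lambda2
}

#' Angle at an interior landmark
#'
#' The angle in degrees at vertex \eqn{P_i} between vectors
#' \eqn{P_i \to P_{i-1}} and \eqn{P_i \to P_{i+1}}, in \[0, 180\].
#'
#' @inheritParams distanceOk
#' @export
angleAt <- function(chain, i) {
  p <- chainPoints(chain)
  if (i < 2 || i > nrow(p) - 1)
    stopf("spineDSS_validation_error", "index %d out of range 2..%d", i, nrow(p) - 1)
  a <- p[i - 1, ] - p[i, ]; b <- p[i + 1, ] - p[i, ]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stopf("spineDSS_geometry_error", "zero-length segment adjacent to index %d", i)
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Constraint violations along a chain
#'
#' Flags each landmark that is deviant under the constraint set: an interior
#' point is deviant when its vertex distance ratio falls outside
#' (\code{lambda1}, \code{lambda2}) or its vertex angle falls outside
#' (\code{theta1Deg}, \code{theta2Deg}\]. A violated constraint at vertex i
#' implicates \eqn{P_i} itself, not its neighbors. Endpoints, which have no
#' ratio or angle of their own, are deviant when their single adjacent
#' segment length departs from the median segment length by more than the
#' lambda band -- unless the adjacent interior vertex is itself deviant, in
#' which case the segment anomaly is already explained and the endpoint is
#' trusted. Landmarks adjacent to a zero-length segment are deviant.
#'
#' @inheritParams distanceOk
#' @return logical vector, one flag per landmark.
#' @export
chainViolations <- function(chain, cfg = constraintConfig()) {
  p <- chainPoints(chain)
  n <- nrow(p)
  if (n < 3)
    stopf("spineDSS_validation_error", "need >= 3 points to evaluate constraints")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  dev <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (seg[i - 1] == 0 || seg[i] == 0) { dev[i] <- TRUE; next }
    r <- seg[i] / seg[i - 1]
    ang <- angleAt(chain, i)
    if (!(r > cfg$lambda1 && r < cfg$lambda2)) dev[i] <- TRUE
    if (!(ang > cfg$theta1Deg && ang <= cfg$theta2Deg)) dev[i] <- TRUE
  }
  med <- stats::median(seg)
  if (med > 0) {
    outband <- function(r) !(r > cfg$lambda1 && r < cfg$lambda2)
    if (outband(seg[1] / med) && !dev[2]) dev[1] <- TRUE
    if (outband(seg[n - 1] / med) && !dev[n - 1]) dev[n] <- TRUE
  }
  dev
}

#' Repair a landmark chain with anatomical constraints
#'
#' Iteratively replaces deviant landmarks (see [chainViolations()]) from
#' their trusted neighbors. Each deviant point is re-estimated linearly (in
#' chain index) from its nearest non-deviant anchors: with clean points on
#' both sides this reduces to interpolation between them (the midpoint of
#' \eqn{P_{i-1}} and \eqn{P_{i+1}} when both immediate neighbors are clean);
#' with clean points on one side only, to extrapolation from the two nearest
#' clean points there (\eqn{P_i = P_{i-1} + (P_{i-1} - P_{i-2})} when they
#' are the immediate cranial pair, or mirrored). A displaced landmark also
#' perturbs the constraints evaluated at its neighbors, so anchors may sit
#' farther than one index away. Endpoints are only ever repaired by
#' extrapolation. Sweeps repeat until the chain is clean or
#' \code{maxRepairIters} is reached (then a warning is raised and
#' \code{converged} is FALSE). Non-deviant points are never moved.
#'
#' @param chain a [PointChain-class] with at least 4 points.
#' @param cfg a [constraintConfig()].
#' @return list with \code{chain} (repaired [PointChain-class]),
#'   \code{repairedIndices} (positions replaced), and \code{converged}.
#' @examples
#' ch <- pointChain(cbind(0, seq(0, 300, by = 60)))
#' pts <- chainPoints(ch); pts[3, 1] <- 30
#' repairChain(pointChain(pts))$repairedIndices
#' @export
repairChain <- function(chain, cfg = constraintConfig()) {
  p <- chainPoints(chain)
  n <- nrow(p)
  if (n < 4)
    stopf("spineDSS_validation_error", "repair needs >= 4 points (got %d)", n)
  repaired <- integer(0)
  converged <- FALSE
  for (iter in seq_len(cfg$maxRepairIters)) {
    dev <- chainViolations(pointChain(p, pixelSpacing(chain)), cfg)
    if (!any(dev)) { converged <- TRUE; break }
    if (all(dev[2:(n - 1)]))
      stopf("spineDSS_unrepairable",
            "every interior landmark violates the constraints; not enough correct reference points")
    newp <- p
    progress <- FALSE
    clean <- which(!dev)
    for (i in which(dev)) {
      left <- clean[clean < i]; right <- clean[clean > i]
      if (length(left) && length(right)) {
        a <- max(left); b <- min(right)
      } else if (length(left) >= 2) {
        a <- left[length(left) - 1]; b <- left[length(left)]
      } else if (length(right) >= 2) {
        a <- right[1]; b <- right[2]
      } else {
        next  # fewer than two trusted anchors on the available side
      }
      newp[i, ] <- p[a, ] + (p[b, ] - p[a, ]) * (i - a) / (b - a)
      repaired <- union(repaired, i)
      progress <- TRUE
    }
    if (!progress) break
    p <- newp
  }
  if (!converged)
    converged <- !any(chainViolations(pointChain(p, pixelSpacing(chain)), cfg))
  if (!converged)
    warnf("spineDSS_repair_incomplete",
          "chain still violates constraints after %d repair sweep(s)",
          cfg$maxRepairIters)
  list(chain = pointChain(p, pixelSpacing(chain)),
       repairedIndices = sort(repaired), converged = converged)
}

#' Localization sensitivity at a distance threshold
#'
#' Fraction of ground-truth landmarks that have a predicted landmark within
#' \code{thresholdMm}, under greedy one-to-one matching (globally nearest
#' pair first). Also reports mean/min/max matched distance in mm over the
#' within-threshold matches.
#'
#' @param pred,truth [PointChain-class] objects; the truth chain's pixel
#'   spacing converts pixels to mm.
#' @param thresholdMm match threshold in mm; default 4.
#' @return list(sensitivity, meanMm, minMm, maxMm, nMatched).
#' @export
localizationSensitivity <- function(pred, truth, thresholdMm = 4) {
  pp <- chainPoints(pred); tp <- chainPoints(truth)
  if (nrow(pp) == 0 || nrow(tp) == 0)
    stopf("spineDSS_validation_error", "both chains must be nonempty")
  sp <- pixelSpacing(truth)
  if (!is.finite(sp) || sp <= 0)
    stopf("spineDSS_unit_error", "truth chain has no valid pixel spacing")
  d <- outer(seq_len(nrow(tp)), seq_len(nrow(pp)),
             function(i, j) sqrt((tp[i, 1] - pp[j, 1])^2 + (tp[i, 2] - pp[j, 2])^2)) * sp
  matched <- numeric(0)
  while (length(d) && any(is.finite(d))) {
    k <- which.min(d)
    i <- (k - 1) %% nrow(d) + 1; j <- (k - 1) %/% nrow(d) + 1
    matched <- c(matched, d[i, j])
    d[i, ] <- Inf; d[, j] <- Inf
    if (all(!is.finite(d))) break
  }
  hits <- matched[matched <= thresholdMm]
  list(sensitivity = length(hits) / nrow(tp),
       meanMm = if (length(hits)) mean(hits) else NA_real_,
       minMm = if (length(hits)) min(hits) else NA_real_,
       maxMm = if (length(hits)) max(hits) else NA_real_,
       nMatched = length(hits))
}
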