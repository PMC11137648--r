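# Hand-crafted texture/shape descriptors for disc grading: histogram of
# pixel intensity (HPI, global darkening from water loss), local binary
# patterns (LBP, texture), and a pyramid histogram of oriented gradients
# (PHOG, shape). Block lengths 64 + 256 + 252 concatenate to the fixed
# 572-dimensional descriptor consumed by the grading MLP.

#' Histogram of pixel intensity
#'
#' Equal-width histogram over the 8-bit range \[0, 255\], normalized to sum 1.
#'
#' @param patch grayscale matrix (8-bit scale).
#' @param bins number of bins; default 64.
#' @return numeric vector of length \code{bins}.
#' @export
extractHPI <- function(patch, bins = 64L) {
  if (length(patch) == 0)
    stopf("spineDSS_validation_error", "patch is empty")
  idx <- pmin(pmax(floor(patch / (256 / bins)), 0), bins - 1)
  tabulate(idx + 1, nbins = bins) / length(patch)
}

# neighbor offsets (dx, dy) in fixed bit order; opposite offsets are 4 bits
# apart, so a 180-degree patch rotation cyclically rotates codes by 4 bits
lbpOffsets <- cbind(dx = c(1, 1, 0, -1, -1, -1, 0, 1),
                    dy = c(0, 1, 1, 1, 0, -1, -1, -1))

#' Local binary pattern histogram
#'
#' 8-neighbor (radius 1) binary codes: bit k is set when the neighbor at the
#' k-th offset is >= the center pixel (ties count as set). Border pixels are
#' excluded; the 256-bin code histogram is normalized to sum 1.
#'
#' @param patch grayscale matrix, at least 3 x 3.
#' @return numeric vector of length 256.
#' @export
extractLBP <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  if (is.null(nr) || nr < 3 || nc < 3)
    stopf("spineDSS_validation_error", "LBP needs a patch of at least 3 x 3")
  rows <- 2:(nr - 1); cols <- 2:(nc - 1)
  ctr <- patch[rows, cols]
  code <- matrix(0, length(rows), length(cols))
  for (k in seq_len(8)) {
    nb <- patch[rows + lbpOffsets[k, "dy"], cols + lbpOffsets[k, "dx"]]
    code <- code + 2^(k - 1) * (nb >= ctr)
  }
  tabulate(code + 1, nbins = 256) / length(code)
}

#' Pyramid histogram of oriented gradients
#'
#' Central-difference gradients (edge-replicated), unsigned orientation in
#' \[0, 180) degrees binned into \code{bins} magnitude-weighted bins, over
#' pyramid levels 0-2 (1 + 4 + 16 cells): \code{bins * 21} values, the whole
#' vector normalized to sum 1. A gradient-free patch returns the uniform
#' vector \code{1/(bins*21)}.
#'
#' @param patch grayscale matrix, at least 8 x 8.
#' @param bins orientation bins; default 12.
#' @param levels pyramid levels; default 0:2.
#' @return numeric vector (length 252 at the defaults).
#' @export
extractPHOG <- function(patch, bins = 12L, levels = 0:2) {
  nr <- nrow(patch); nc <- ncol(patch)
  if (is.null(nr) || nr < 8 || nc < 8)
    stopf("spineDSS_validation_error", "PHOG needs a patch of at least 8 x 8")
  padX <- patch[, c(1, seq_len(nc), nc)]
  padY <- patch[c(1, seq_len(nr), nr), ]
  gx <- (padX[, 3:(nc + 2)] - padX[, 1:nc]) / 2
  gy <- (padY[3:(nr + 2), ] - padY[1:nr, ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- (atan2(gy, gx) * 180 / pi) %% 180
  bin <- pmin(floor(ori / (180 / bins)), bins - 1)
  out <- numeric(0)
  for (l in levels) {
    k <- 2^l
    rIdx <- ceiling(seq_len(nr) / (nr / k))
    cIdx <- ceiling(seq_len(nc) / (nc / k))
    for (rc in seq_len(k)) for (cc in seq_len(k)) {
      sel <- outer(rIdx == rc, cIdx == cc, FUN = "&")
      h <- numeric(bins)
      if (any(sel)) {
        b <- bin[sel]; w <- mag[sel]
        for (j in which(tabulate(b + 1, bins) > 0))
          h[j] <- sum(w[b == j - 1])
      }
      out <- c(out, h)
    }
  }
  tot <- sum(out)
  if (tot == 0) rep(1 / length(out), length(out)) else out / tot
}

#' Fixed block split of the 572-dimensional descriptor
#' @export
featureBlockSpans <- function() c(hpi = 64L, lbp = 256L, phog = 252L)

#' Build the 572-dimensional disc descriptor
#'
#' Concatenates HPI (64), LBP (256) and PHOG (252) in that fixed order; each
#' block sums to 1 before any model-side standardization.
#'
#' @param patch grayscale matrix, at least 8 x 8.
#' @return numeric vector of length exactly 572, with attribute
#'   \code{blockSpans}.
#' @export
buildFeatureVector <- function(patch) {
  spans <- featureBlockSpans()
  fv <- c(extractHPI(patch, spans["hpi"]), extractLBP(patch),
          extractPHOG(patch))
  stopifnot(length(fv) == sum(spans))
  attr(fv, "blockSpans") <- spans
  fv
}
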