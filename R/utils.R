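# Internal helpers: typed conditions, seeded evaluation, raster resampling.

stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "spineDSS_error", "error", "condition")))
}

warnf <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "spineDSS_warning", "warning", "condition")))
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# 0-based pixel coordinates throughout: x = column, y = row; a raster is a
# base matrix indexed [y + 1, x + 1]. Pixel centers sit on integer coordinates.
sampleBilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  px <- function(xx, yy) {
    v <- numeric(length(xx))
    ok <- xx >= 0 & xx <= nc - 1 & yy >= 0 & yy <= nr - 1
    if (any(ok)) v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  (1 - fx) * (1 - fy) * px(x0, y0) +
    fx * (1 - fy) * px(x0 + 1, y0) +
    (1 - fx) * fy * px(x0, y0 + 1) +
    fx * fy * px(x0 + 1, y0 + 1)
}

# Resample an oriented rectangle. origin is one corner; u/v are unit vectors
# spanning the rectangle; the patch has nU rows (along u) and nV columns
# (along v), sampled at cell centers. Out-of-image samples read as 0.
cropOriented <- function(image, origin, u, v, uLen, vLen, nU, nV) {
  us <- (seq_len(nU) - 0.5) / nU * uLen
  vs <- (seq_len(nV) - 0.5) / nV * vLen
  gx <- origin[1] + outer(us * u[1], rep(1, nV)) + outer(rep(1, nU), vs * v[1])
  gy <- origin[2] + outer(us * u[2], rep(1, nV)) + outer(rep(1, nU), vs * v[2])
  matrix(sampleBilinear(image, as.vector(gx), as.vector(gy)), nU, nV)
}

# Rotate a raster about its center by deg (counter-clockwise in pixel axes),
# bilinear interpolation, same output size, background 0.
rotateImage <- function(image, deg) {
  if (deg == 0) return(image)
  nr <- nrow(image); nc <- ncol(image)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  th <- deg * pi / 180
  xs <- 0:(nc - 1); ys <- 0:(nr - 1)
  gx <- outer(ys * 0, xs, FUN = function(a, b) b)
  gy <- outer(ys, xs * 0, FUN = function(a, b) a)
  dx <- gx - cx; dy <- gy - cy
  sx <- cos(th) * dx + sin(th) * dy + cx
  sy <- -sin(th) * dx + cos(th) * dy + cy
  matrix(sampleBilinear(image, as.vector(sx), as.vector(sy)), nr, nc)
}

unitVec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("spineDSS_geometry_error", "cannot normalize a zero vector")
  v / n
}

# +90 degree rotation of a 2-vector (x right, y down convention).
rot90vec <- function(v) c(-v[2], v[1])

clip255 <- function(img) pmin(pmax(img, 0), 255)

# Coordinate grids for an nr x nc raster (0-based; Xg holds column index).
pixelGrids <- function(nr, nc) {
  list(x = matrix(rep(0:(nc - 1), each = nr), nr, nc),
       y = matrix(rep(0:(nr - 1), times = nc), nr, nc))
}

isPoint <- function(p) is.numeric(p) && length(p) == 2 && all(is.finite(p))
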