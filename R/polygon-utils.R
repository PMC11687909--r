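# Planar polygon primitives shared by the synthetic generator, the contour
# extractor and the morphology descriptors. Polygons are n x 2 matrices of
# (x, y) vertices, implicitly closed (last vertex connects back to the
# first), in pixel units with x = column and y = row.

poly_check <- function(xy, min_vertices = 3L) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < min_vertices || !all(is.finite(xy)))
    stop_macmot("polygon must be a finite n x 2 matrix with n >= ", min_vertices)
  # drop an explicitly repeated closing vertex
  n <- nrow(xy)
  if (n > min_vertices && all(xy[1L, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  unname(xy)
}

poly_signed_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(xy) abs(poly_signed_area(poly_check(xy)))

poly_perimeter <- function(xy) {
  xy <- poly_check(xy)
  d <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

# Orient counter-clockwise in the (x, y) axes convention (positive signed
# area). Note image rows increase downwards; orientation is defined on the
# coordinate values themselves.
poly_orient_ccw <- function(xy) {
  xy <- poly_check(xy)
  if (poly_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

# Area, centroid and per-unit-area central second moments of a simple
# polygon via Green's theorem.
poly_moments <- function(xy) {
  xy <- poly_check(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps^0.5)
    stop_macmot("degenerate polygon with (near) zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # second moments about the origin, then shifted to the centroid
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12        # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12        # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  s <- sign(a)
  list(
    area = abs(a),
    centroid = c(x = cx, y = cy),
    mu20 = s * iyy / abs(a) - cx^2,
    mu02 = s * ixx / abs(a) - cy^2,
    mu11 = s * ixy / abs(a) - cx * cy
  )
}

# Eccentricity of the moment-equivalent ellipse from central second moments
# (per unit area). Shared by the polygon and pixel-set routes.
moments_to_eccentricity <- function(mu20, mu02, mu11) {
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- max(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  if (l1 <= .Machine$double.eps) return(structure(0, degenerate = TRUE))
  ratio <- max(l2, 0) / l1
  e <- sqrt(1 - ratio)
  if (l2 <= .Machine$double.eps * tr) {
    # collinear mass: cap strictly below 1 and flag
    return(structure(min(e, 1 - 1e-9), degenerate = TRUE))
  }
  min(e, 1 - 1e-12)
}

# Pixel-set central moments (pixel centres, unit mass per pixel).
pixel_moments <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  cx <- mean(xy[, 1L]); cy <- mean(xy[, 2L])
  dx <- xy[, 1L] - cx; dy <- xy[, 2L] - cy
  list(area = n, centroid = c(x = cx, y = cy),
       mu20 = sum(dx^2) / n, mu02 = sum(dy^2) / n, mu11 = sum(dx * dy) / n)
}

convex_hull <- function(xy) {
  xy <- as.matrix(xy)
  h <- chull(xy[, 1L], xy[, 2L])
  xy[h, , drop = FALSE]
}

convex_hull_area <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) return(0)
  h <- convex_hull(xy)
  if (nrow(h) < 3L) return(0)
  abs(poly_signed_area(h))
}

# Resample a closed polygon to n points equally spaced by arc length,
# keeping the current starting vertex.
resample_closed <- function(xy, n) {
  xy <- poly_check(xy)
  p <- rbind(xy, xy[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  keep <- c(TRUE, seg > 0)            # collapse duplicated vertices
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 4L) stop_macmot("degenerate contour: fewer than 3 distinct vertices")
  d <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  len <- d[length(d)]
  s <- seq(0, len, length.out = n + 1L)[seq_len(n)]
  cbind(approx(d, p[, 1L], s)$y, approx(d, p[, 2L], s)$y)
}

# Circular Gaussian smoothing of a closed, evenly resampled polygon.
# sd is in units of sample spacing.
smooth_closed <- function(xy, sd = 1) {
  if (sd <= 0) return(xy)
  n <- nrow(xy)
  hw <- max(1L, ceiling(3 * sd))
  w <- dnorm(-hw:hw, sd = sd)
  w <- w / sum(w)
  pad <- function(v) c(v[(n - hw + 1L):n], v, v[1L:hw])
  sm <- function(v) stats::filter(pad(v), w, sides = 2)[(hw + 1L):(hw + n)]
  cbind(as.numeric(sm(xy[, 1L])), as.numeric(sm(xy[, 2L])))
}

#' @importFrom stats approx dnorm
NULL
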