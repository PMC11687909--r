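# Morphology descriptors. Conventions:
#   eccentricity  sqrt(1 - (b/a)^2) of the moment-equivalent ellipse,
#                 from pixel-set second moments for regions and from exact
#                 polygon (Green's theorem) moments for contours;
#   solidity      contour area / area of the convex hull of the contour;
#   compactness   4*pi*A/P^2 (isoperimetric quotient) on the sub-pixel
#                 contour, clipped to <= 1 (discretization can push a near
#                 disk a fraction of a percent above 1).
# For classification, descriptors are taken at a cell's first frame.

#' Eccentricity of a region or contour
#'
#' `sqrt(1 - (b/a)^2)` where a, b are the major/minor semi-axes of the
#' ellipse with the same second central moments. 0 for a disk, -> 1 for
#' thin elongated shapes. Degenerate (collinear) inputs return a value
#' capped just below 1 with attribute `degenerate = TRUE`.
#'
#' @param x a `region` (pixel moments) or an n x 2 contour polygon
#'   (exact polygon moments).
#' @return Eccentricity in \[0, 1).
#' @export
shape_eccentricity <- function(x) {
  mu <- if (inherits(x, "region")) {
    if (x$area_px < 1L) stop_macmot("empty region")
    pixel_moments(region_pixels(x))
  } else {
    poly_moments(poly_check(x))
  }
  moments_to_eccentricity(mu$mu20, mu$mu02, mu$mu11)
}

#' Solidity of a region or contour
#'
#' Area divided by the area of the convex hull; 1 for convex shapes, low
#' values indicate protrusions or concavities.
#'
#' @inheritParams shape_eccentricity
#' @param ... passed to [region_to_contour()] for region input.
#' @return Solidity in (0, 1\].
#' @export
shape_solidity <- function(x, ...) {
  xy <- if (inherits(x, "region")) region_to_contour(x, ...) else poly_check(x)
  a <- poly_area(xy)
  h <- convex_hull_area(xy)
  if (h <= 0) stop_macmot("degenerate contour: zero hull area")
  min(a / h, 1)
}

#' Compactness (isoperimetric quotient) of a region or contour
#'
#' `4*pi*A / P^2`: 1 for a disk, lower for irregular boundaries. Values
#' pushed above 1 by discretization (at most ~2% for tiny regions) are
#' clipped to 1 with attribute `clipped = TRUE`.
#'
#' @inheritParams shape_solidity
#' @export
shape_compactness <- function(x, ...) {
  xy <- if (inherits(x, "region")) region_to_contour(x, ...) else poly_check(x)
  p <- poly_perimeter(xy)
  if (p <= 0) stop_macmot("zero-perimeter contour")
  q <- 4 * pi * poly_area(xy) / p^2
  if (q > 1) structure(1, clipped = TRUE, raw = q) else q
}

# shared by morph_features() and the analytic cohort route: descriptors of
# a polygon outline under the package contour convention (200-point
# equal-arc resampling + light smoothing), cell size = polygon area.
contour_morphology <- function(xy, n_points = 200L, smooth_sd = 1) {
  xy <- resample_closed(poly_check(xy), n_points)
  if (smooth_sd > 0) xy <- smooth_closed(xy, smooth_sd)
  list(eccentricity = as.numeric(shape_eccentricity(xy)),
       solidity = shape_solidity(xy),
       compactness = as.numeric(shape_compactness(xy)),
       cell_size = poly_area(xy))
}

#' Morphology descriptors of one cell track
#'
#' Computes eccentricity, solidity, compactness and cell size on the
#' region of the selected frame. The default (and the convention used for
#' subtype classification) is the first frame of the track; morphology at
#' later frames matters only for shape-mode analysis, which works on raw
#' contours instead.
#'
#' @param track a `cell_track` with region masks.
#' @param frame_policy `"first"` or an integer index into the track's
#'   frames.
#' @return A one-row data frame: `eccentricity`, `solidity`,
#'   `compactness`, `cell_size` (pixel count of the region).
#' @export
morph_features <- function(track, frame_policy = "first") {
  stopifnot(inherits(track, "cell_track"))
  if (is.null(track$regions))
    stop_macmot("track carries no region masks; morphology unavailable")
  i <- if (identical(frame_policy, "first")) 1L else as.integer(frame_policy)
  if (i < 1L || i > length(track$regions) || is.null(track$regions[[i]]))
    stop_macmot("no region at the requested frame for cell ", track$cell_id)
  reg <- track$regions[[i]]
  ctr <- region_to_contour(reg)
  data.frame(
    eccentricity = as.numeric(shape_eccentricity(reg)),
    solidity = shape_solidity(ctr),
    compactness = as.numeric(shape_compactness(ctr)),
    cell_size = reg$area_px
  )
}
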