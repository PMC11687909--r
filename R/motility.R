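# Motility descriptors of a single-cell trajectory.
#
# speed        total path length / elapsed time (px/min);
# persistence  net displacement from the start / total path length, the
#              directionality ratio in [0, 1];
# hull area    area of the convex hull of all trajectory points (px^2).
#
# Both speed and persistence are defined "up to" any frame from 2 to n, so
# each cell has a time series plus a final whole-track scalar; the scalars
# are what clustering, discrimination and classification consume.

path_lengths <- function(xy) {
  sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
}

#' Speed of a trajectory
#'
#' Total path length up to frame `upto` divided by the elapsed time
#' `(upto - 1) * frame_interval_min`.
#'
#' @param xy n x 2 matrix of trajectory points (pixels).
#' @param frame_interval_min frame interval, minutes.
#' @param upto endpoint frame (2..n); default the last point.
#' @return Speed in px/min.
#' @export
track_speed <- function(xy, frame_interval_min = 5, upto = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  upto <- upto %||% n
  if (n < 2L || upto < 2L || upto > n)
    stop_macmot("speed needs at least 2 trajectory points (2 <= upto <= n)")
  sum(path_lengths(xy[seq_len(upto), , drop = FALSE])) /
    ((upto - 1) * frame_interval_min)
}

#' @rdname track_speed
#' @return `speed_series()`: speeds at every endpoint 2..n.
#' @export
speed_series <- function(xy, frame_interval_min = 5) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) stop_macmot("speed needs at least 2 trajectory points")
  cumsum(path_lengths(xy)) / (seq_len(nrow(xy) - 1L) * frame_interval_min)
}

#' Persistence (directionality ratio) of a trajectory
#'
#' Net displacement between the first point and the point at frame `upto`,
#' divided by the path length up to `upto`. Always in \[0, 1\]: 1 for a
#' straight monotone path, 0 for a closed loop. A zero-length path has
#' undefined direction; the convention here is 0 with attribute
#' `zero_path = TRUE`.
#'
#' @inheritParams track_speed
#' @export
track_persistence <- function(xy, upto = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  upto <- upto %||% n
  if (n < 2L || upto < 2L || upto > n)
    stop_macmot("persistence needs at least 2 trajectory points (2 <= upto <= n)")
  seg <- path_lengths(xy[seq_len(upto), , drop = FALSE])
  d <- sum(seg)
  if (d <= 0) return(structure(0, zero_path = TRUE))
  p <- sqrt(sum((xy[upto, ] - xy[1L, ])^2))
  min(p / d, 1)
}

#' @rdname track_persistence
#' @export
persistence_series <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) stop_macmot("persistence needs at least 2 trajectory points")
  seg <- cumsum(path_lengths(xy))
  net <- sqrt(rowSums(sweep(xy[-1L, , drop = FALSE], 2L, xy[1L, ], "-")^2))
  ifelse(seg > 0, pmin(net / seg, 1), 0)
}

#' Convex-hull area of the trajectory points
#'
#' Area of the convex hull spanned by every visited position: a measure of
#' how much territory a cell has explored. 0 for fewer than 3 distinct
#' non-collinear points.
#'
#' @param xy n x 2 matrix of trajectory points.
#' @return Area in px^2.
#' @export
trajectory_hull_area <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) return(0)
  convex_hull_area(xy)
}

#' All motility descriptors for one cell
#'
#' @param track a `cell_track`, or an n x 2 trajectory matrix.
#' @param frame_interval_min frame interval (ignored when `track` is a
#'   `cell_track`, which carries its own).
#' @return List with `speed_series`, `persistence_series` (endpoints
#'   2..n), `speed_final`, `persistence_final`, `hull_area_px2`.
#' @export
motility_features <- function(track, frame_interval_min = 5) {
  if (inherits(track, "cell_track")) {
    xy <- track$centroids
    frame_interval_min <- track$frame_interval_min
  } else xy <- as.matrix(track)
  if (nrow(xy) < 2L)
    stop_macmot("motility undefined for tracks shorter than 2 frames")
  sp <- speed_series(xy, frame_interval_min)
  pe <- persistence_series(xy)
  structure(list(
    speed_series = sp,
    persistence_series = pe,
    speed_final = sp[length(sp)],
    persistence_final = pe[length(pe)],
    hull_area_px2 = trajectory_hull_area(xy)
  ), class = "motility_features")
}
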