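# Principal shape-mode analysis of cell outlines: every outline is
# resampled to a fixed number of equally spaced arc-length points,
# outlines are mutually aligned by generalized Procrustes analysis
# (translation + rotation, with point correspondence optimized over
# cyclic shifts and traversal reflection), and principal components of
# the aligned coordinates give the dominant modes of shape variation.

#' Resample a contour to equally spaced arc-length points
#'
#' The starting point is canonicalized to the vertex farthest from the
#' centroid (ties: first such vertex), which makes resampling idempotent;
#' residual start-point ambiguity is absorbed by the cyclic-shift search
#' in [align_shapes()]. Orientation is normalized counter-clockwise.
#'
#' @param contour n x 2 closed polygon.
#' @param n_points number of output points (default 200).
#' @return An `n_points` x 2 matrix.
#' @export
resample_contour <- function(contour, n_points = 200L) {
  xy <- poly_orient_ccw(poly_check(contour))
  ctr <- poly_moments(xy)$centroid
  d2 <- (xy[, 1L] - ctr[1L])^2 + (xy[, 2L] - ctr[2L])^2
  s <- which.max(d2)
  if (s > 1L) xy <- xy[c(s:nrow(xy), 1L:(s - 1L)), , drop = FALSE]
  resample_closed(xy, n_points)
}

# inner products of m with all cyclic shifts of z (complex n-vectors),
# via FFT: ip[s+1] = sum_k m_k * Conj(z_{k+s})
shift_inner_products <- function(z, m) {
  n <- length(z)
  fft(fft(Conj(z)) * Conj(fft(Conj(m))), inverse = TRUE) / n
}

best_cyclic_alignment <- function(z, m) {
  cand <- list(list(z = z, reflected = FALSE),
               list(z = rev(Conj(z)), reflected = TRUE))
  best <- NULL
  for (cc in cand) {
    ip <- shift_inner_products(cc$z, m)
    s <- which.max(Mod(ip)) - 1L
    if (is.null(best) || Mod(ip[s + 1L]) > best$gain) {
      rot <- ip[s + 1L] / Mod(ip[s + 1L])
      best <- list(shift = s, reflected = cc$reflected,
                   rotation = rot, gain = Mod(ip[s + 1L]), z = cc$z)
    }
  }
  n <- length(z)
  idx <- ((seq_len(n) - 1L + best$shift) %% n) + 1L
  best$aligned <- best$rotation * best$z[idx]
  best
}

#' Generalized Procrustes alignment of resampled outlines
#'
#' Outlines are translated to a common centroid (the origin) and
#' iteratively rotated to minimize summed squared distance to the evolving
#' mean shape; point correspondence is optimized over cyclic shifts and
#' traversal reflection at every step (computed in closed form via the
#' FFT). Scale is retained by default because cell size is biologically
#' meaningful; set `scale = "unit"` to normalize each outline to unit
#' centroid size.
#'
#' @param outlines list of n x 2 matrices with a common n (e.g. from
#'   [resample_contour()]).
#' @param scale `"none"` (default) or `"unit"`.
#' @param max_iter,tol iteration cap and relative mean-change tolerance.
#' @return Object of class `aligned_shapes`: list with `shapes`
#'   (N x n x 2 array), `mean_shape`, `alignment` (per-shape shift,
#'   reflection, rotation angle), `converged`, `iterations`.
#' @export
align_shapes <- function(outlines, scale = c("none", "unit"),
                         max_iter = 100L, tol = 1e-8) {
  scale <- match.arg(scale)
  if (length(outlines) < 2L) stop_macmot("need at least 2 outlines")
  npts <- unique(vapply(outlines, nrow, 0L))
  if (length(npts) != 1L) stop_macmot("all outlines must have the same point count")
  zs <- lapply(outlines, function(p) {
    z <- complex(real = p[, 1L], imaginary = p[, 2L])
    z <- z - mean(z)
    if (scale == "unit") z <- z / sqrt(mean(Mod(z)^2))
    z
  })
  m <- zs[[1L]]
  converged <- FALSE
  iter <- 0L
  aligned <- zs
  for (iter in seq_len(max_iter)) {
    fits <- lapply(zs, best_cyclic_alignment, m = m)
    aligned <- lapply(fits, `[[`, "aligned")
    m_new <- Reduce(`+`, aligned) / length(aligned)
    m_new <- m_new - mean(m_new)
    delta <- sqrt(sum(Mod(m_new - m)^2)) / max(sqrt(sum(Mod(m)^2)), 1e-12)
    m <- m_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Procrustes alignment did not converge in ", max_iter,
            " iterations; returning the best iterate")
  fits <- lapply(zs, best_cyclic_alignment, m = m)
  arr <- array(0, dim = c(length(zs), npts, 2L))
  for (i in seq_along(fits)) {
    arr[i, , 1L] <- Re(fits[[i]]$aligned)
    arr[i, , 2L] <- Im(fits[[i]]$aligned)
  }
  structure(list(
    shapes = arr,
    mean_shape = cbind(Re(m), Im(m)),
    alignment = data.frame(
      shift = vapply(fits, `[[`, 0L, "shift"),
      reflected = vapply(fits, `[[`, TRUE, "reflected"),
      rotation_rad = vapply(fits, function(f) Arg(f$rotation), 0)
    ),
    scale = scale, converged = converged, iterations = iter
  ), class = "aligned_shapes")
}

#' Principal modes of shape variation
#'
#' Eigen-decomposition of the covariance of the flattened aligned
#' coordinates (PCA). Modes are orthonormal directions in the
#' 2n-dimensional shape space, ordered by explained variance.
#'
#' @param aligned an [align_shapes()] result.
#' @param n_modes number of modes to retain (default 3).
#' @return Object of class `shape_mode_model`: `mean_shape` (n x 2),
#'   `modes` (2n x n_modes, orthonormal), `variance_fractions`,
#'   `mode_sd` (SD of the scores along each mode), `scores`
#'   (N x n_modes), `eigenvalues` (all).
#' @export
fit_shape_modes <- function(aligned, n_modes = 3L) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  dims <- dim(aligned$shapes)
  n_shapes <- dims[1L]; npts <- dims[2L]
  if (n_shapes < n_modes + 1L)
    stop_macmot("need at least n_modes + 1 shapes")
  x <- cbind(aligned$shapes[, , 1L], aligned$shapes[, , 2L])
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= .Machine$double.eps) {
    warning("zero-variance shape set: no modes")
    return(structure(list(
      mean_shape = cbind(colMeans(x)[1:npts], colMeans(x)[npts + 1:npts]),
      modes = matrix(0, 2L * npts, 0L), variance_fractions = numeric(0),
      mode_sd = numeric(0), scores = matrix(0, n_shapes, 0L),
      eigenvalues = ev, zero_variance = TRUE
    ), class = "shape_mode_model"))
  }
  rank <- sum(ev > ev[1L] * 1e-12)
  if (rank < n_modes) {
    warning("rank-deficient shape set: returning ", rank,
            " modes instead of ", n_modes)
    n_modes <- rank
  }
  keep <- seq_len(n_modes)
  structure(list(
    mean_shape = cbind(colMeans(x)[1:npts], colMeans(x)[npts + 1:npts]),
    modes = pc$rotation[, keep, drop = FALSE],
    variance_fractions = ev[keep] / total,
    mode_sd = pc$sdev[keep],
    scores = pc$x[, keep, drop = FALSE],
    eigenvalues = ev
  ), class = "shape_mode_model")
}

#' Reconstruct a shape along one mode
#'
#' Returns the mean shape displaced `k_sd` score standard deviations along
#' the given mode; `k_sd = 0` reproduces the mean shape exactly.
#'
#' @param model a [fit_shape_modes()] result.
#' @param mode mode index.
#' @param k_sd displacement in score SDs (typically -2..2).
#' @return n x 2 outline matrix.
#' @export
reconstruct_shape <- function(model, mode = 1L, k_sd = 0) {
  stopifnot(inherits(model, "shape_mode_model"))
  if (mode < 1L || mode > ncol(model$modes)) stop_macmot("no such mode")
  npts <- nrow(model$mean_shape)
  v <- model$modes[, mode] * model$mode_sd[mode] * k_sd
  model$mean_shape + cbind(v[1:npts], v[npts + 1:npts])
}

#' @export
print.shape_mode_model <- function(x, ...) {
  cat("shape_mode_model:", ncol(x$modes), "modes over",
      nrow(x$scores), "shapes\n")
  if (length(x$variance_fractions))
    cat("variance fractions:",
        paste(sprintf("%.1f%%", 100 * x$variance_fractions), collapse = ", "),
        sprintf("(top-%d total %.1f%%)\n", ncol(x$modes),
                100 * sum(x$variance_fractions)))
  invisible(x)
}
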