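# Independent brute-force oracles used to check the package's geometry
# and statistics code. These are written naively on purpose and share no
# code with the implementation.

# shoelace area via an explicit loop
oracle_poly_area <- function(xy) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + xy[i, 1] * xy[j, 2] - xy[j, 1] * xy[i, 2]
  }
  abs(s) / 2
}

oracle_perimeter <- function(xy) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + sqrt(sum((xy[j, ] - xy[i, ])^2))
  }
  s
}

# gift-wrapping convex hull (O(n*h)), then shoelace
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1L]
    for (r in cand[-1L]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("hull oracle failed to terminate")
  }
  if (length(hull) < 3L) return(0)
  oracle_poly_area(pts[hull, , drop = FALSE])
}

# naive speed / persistence
oracle_speed <- function(xy, dt) {
  s <- 0
  for (i in seq_len(nrow(xy) - 1L))
    s <- s + sqrt(sum((xy[i + 1L, ] - xy[i, ])^2))
  s / ((nrow(xy) - 1L) * dt)
}

oracle_persistence <- function(xy) {
  d <- 0
  for (i in seq_len(nrow(xy) - 1L))
    d <- d + sqrt(sum((xy[i + 1L, ] - xy[i, ])^2))
  if (d == 0) return(0)
  sqrt(sum((xy[nrow(xy), ] - xy[1L, ])^2)) / d
}

# Gaussian log-posterior QDA rule, written directly from the definition
oracle_qda_predict <- function(x_train, y_train, x_test) {
  y_train <- factor(y_train)
  cls <- levels(y_train)
  stats <- lapply(cls, function(cl) {
    xi <- x_train[y_train == cl, , drop = FALSE]
    mu <- colMeans(xi)
    sig <- matrix(0, ncol(xi), ncol(xi))
    for (i in seq_len(nrow(xi)))
      sig <- sig + tcrossprod(xi[i, ] - mu)
    sig <- sig / nrow(xi)
    list(mu = mu, sig = sig, prior = nrow(xi) / nrow(x_train))
  })
  pred <- character(nrow(x_test))
  for (i in seq_len(nrow(x_test))) {
    lp <- vapply(stats, function(s) {
      d <- x_test[i, ] - s$mu
      log(s$prior) - 0.5 * log(det(s$sig)) -
        0.5 * as.numeric(t(d) %*% solve(s$sig) %*% d)
    }, 0)
    pred[i] <- cls[which.max(lp)]
  }
  factor(pred, levels = cls)
}

# pixel mask of a disk, as a ready-made region object
disk_region <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  g <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix((g$col - ctr)^2 + (g$row - ctr)^2 <= r^2, n, n)
  mask_to_region(m)
}

square_region <- function(side, pad = 3L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  mask_to_region(m)
}

ellipse_region <- function(a, b, pad = 3L) {
  nr <- 2L * (b + pad) + 1L; nc <- 2L * (a + pad) + 1L
  cy <- b + pad + 1L; cx <- a + pad + 1L
  g <- expand.grid(row = 1:nr, col = 1:nc)
  m <- matrix(((g$col - cx) / a)^2 + ((g$row - cy) / b)^2 <= 1, nr, nc)
  mask_to_region(m)
}

mask_to_region <- function(m) {
  st <- label_stack(list(matrix(as.integer(m), nrow(m), ncol(m))))
  extract_regions(st)[[1L]]
}

# small well-separated 4-archetype morphology table for k-selection tests
morph_blobs <- function(n_per = 50L, seed = 5L) {
  arcs <- default_archetypes(c("circular", "protruded", "elongated", "mixed"))
  tight <- default_cell_variability(radius_sd = 0.05, step_sd = 0.05,
                                    turn_sd = 0.05, aspect_sd = 0.08,
                                    depth_sd = 0.05)
  macmot:::local_seed(seed, {
    rows <- lapply(names(arcs), function(nm) {
      do.call(rbind, lapply(seq_len(n_per), function(i) {
        p <- macmot:::jitter_archetype(arcs[[nm]], tight)
        m <- macmot:::contour_morphology(make_shape(p))
        data.frame(archetype = nm, eccentricity = m$eccentricity,
                   solidity = m$solidity, compactness = m$compactness)
      }))
    })
    do.call(rbind, rows)
  })
}
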