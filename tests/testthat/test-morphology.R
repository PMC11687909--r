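# Shape descriptors against closed forms, pixel-moment oracles and
# invariance properties.

test_that("descriptors hit their closed forms on analytic shapes", {
  disk <- disk_region(30L)
  expect_equal(as.numeric(shape_compactness(disk)), 1, tolerance = 0.02)
  expect_equal(shape_solidity(disk), 1, tolerance = 0.01)
  expect_lt(as.numeric(shape_eccentricity(disk)), 0.05)
  # square: compactness pi/4 (5% discretization band at 20 px)
  sq <- square_region(20L)
  expect_equal(as.numeric(shape_compactness(sq)), pi / 4, tolerance = 0.05)
  expect_equal(shape_solidity(sq), 1, tolerance = 0.01)
  # a/b = 5 ellipse: eccentricity sqrt(24)/5
  ell <- ellipse_region(50L, 10L)
  expect_equal(as.numeric(shape_eccentricity(ell)), sqrt(24) / 5,
               tolerance = 0.01)
})

test_that("region eccentricity equals the direct pixel-moment computation", {
  set.seed(41)
  img <- matrix(0L, 40L, 40L)
  img[10:30, 10:30][matrix(runif(441), 21L) > 0.35] <- 1L
  regs <- extract_regions(label_stack(list(img)))
  reg <- regs[[which.max(vapply(regs, `[[`, 0L, "area_px"))]]
  px <- macmot:::region_pixels(reg)
  n <- nrow(px)
  mu20 <- sum((px[, 1] - mean(px[, 1]))^2) / n
  mu02 <- sum((px[, 2] - mean(px[, 2]))^2) / n
  mu11 <- sum((px[, 1] - mean(px[, 1])) * (px[, 2] - mean(px[, 2]))) / n
  tr <- mu20 + mu02
  l1 <- tr / 2 + sqrt(tr^2 / 4 - (mu20 * mu02 - mu11^2))
  l2 <- tr / 2 - sqrt(tr^2 / 4 - (mu20 * mu02 - mu11^2))
  expect_equal(as.numeric(shape_eccentricity(reg)), sqrt(1 - l2 / l1),
               tolerance = 1e-9)
})

test_that("star polygons have lower compactness than their hulls and solidity matches the oracle", {
  set.seed(42)
  star <- make_shape(archetype_params("protruded", radius_px = 20,
                                      n_protrusions = 6,
                                      protrusion_depth = 0.5), 240L)
  hull <- macmot:::convex_hull(star)
  expect_lt(as.numeric(shape_compactness(star)),
            as.numeric(shape_compactness(hull)))
  expect_equal(shape_solidity(star),
               oracle_poly_area(star) / oracle_hull_area(star),
               tolerance = 1e-6)
  expect_lte(shape_solidity(star), 1)
})

test_that("descriptors are scale- and rotation-invariant; size scales as area", {
  base <- ellipse_region(30L, 15L)
  up <- ellipse_region(60L, 30L)     # 2x upsampled
  for (f in list(shape_eccentricity, shape_compactness, shape_solidity)) {
    expect_equal(as.numeric(f(base)), as.numeric(f(up)), tolerance = 0.02)
  }
  expect_equal(up$area_px / base$area_px, 4, tolerance = 0.02)
  # rotation by 30 degrees (rasterized rotated ellipse)
  th <- pi / 6
  g <- expand.grid(row = 1:150, col = 1:150)
  xr <- (g$col - 75) * cos(th) + (g$row - 75) * sin(th)
  yr <- -(g$col - 75) * sin(th) + (g$row - 75) * cos(th)
  rot <- matrix((xr / 30)^2 + (yr / 15)^2 <= 1, 150L, 150L)
  reg_rot <- mask_to_region(rot)
  for (f in list(shape_eccentricity, shape_compactness, shape_solidity)) {
    expect_equal(as.numeric(f(base)), as.numeric(f(reg_rot)), tolerance = 0.03)
  }
})

test_that("degenerate inputs error (contours) or are capped and flagged (regions)", {
  expect_error(shape_compactness(cbind(c(0, 1), c(0, 0))), "polygon")
  expect_error(macmot:::poly_moments(cbind(c(0, 1, 2), c(0, 0, 0))),
               "degenerate")
  # collinear pixel mass: eccentricity capped below 1 and flagged
  img <- matrix(0L, 5L, 20L)
  img[3L, 2:19] <- 1L
  line <- extract_regions(label_stack(list(img)))[[1L]]
  e <- shape_eccentricity(line)
  expect_lt(as.numeric(e), 1)
  expect_true(isTRUE(attr(e, "degenerate")))
})

test_that("archetype cohorts separate in the catalogued directions", {
  set.seed(77)
  arcs <- default_archetypes()
  vals <- lapply(arcs, function(p) {
    do.call(rbind, lapply(1:40, function(i) {
      m <- macmot:::contour_morphology(
        make_shape(macmot:::jitter_archetype(p, default_cell_variability())))
      data.frame(ecc = m$eccentricity, sol = m$solidity, comp = m$compactness)
    }))
  })
  means <- t(sapply(vals, colMeans))
  # circular: compact, solid, round
  expect_gte(means["circular", "comp"], 0.9)
  expect_lte(means["circular", "ecc"], 0.4)
  expect_gte(means["circular", "sol"], 0.95)
  # elongated: highest eccentricity; protruded: lowest solidity
  expect_equal(rownames(means)[which.max(means[, "ecc"])], "elongated")
  expect_equal(rownames(means)[which.min(means[, "sol"])], "protruded")
})

test_that("morph_features uses the first frame and propagates errors", {
  coh <- render_cohort(synthetic_config("M0", n_cells = 2L, n_frames = 3L,
                                        image_size_px = c(256L, 256L),
                                        rng_seed = 6L))
  trks <- link_tracks(extract_regions(coh$stack), parent_label = "M0")
  mf <- morph_features(trks[[1L]])
  expect_named(mf, c("eccentricity", "solidity", "compactness", "cell_size"))
  expect_equal(mf$cell_size, trks[[1L]]$regions[[1L]]$area_px)
  bare <- macmot:::new_cell_track(9L, "M0", 1:3, cbind(1:3, 1:3))
  expect_error(morph_features(bare), "no region masks")
})
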