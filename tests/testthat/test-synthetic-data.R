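# Synthetic generator: shape geometry, trajectory statistics, rendering.

test_that("archetype parameter validation rejects degenerate inputs", {
  expect_error(archetype_params("circular", radius_px = 0), "positive")
  expect_error(archetype_params("circular", radius_px = 10, aspect_ratio = 2),
               "aspect_ratio")
  expect_error(archetype_params("protruded", radius_px = 10,
                                n_protrusions = 6, protrusion_depth = 1.2),
               "protrusion_depth")
  expect_error(archetype_params("elongated", radius_px = 10,
                                aspect_ratio = 0.5), "aspect_ratio")
})

test_that("noise-free shapes match closed-form geometry", {
  set.seed(1)
  # ideal disk: isoperimetric quotient of the polygon approaches 1
  circ <- make_shape(archetype_params("circular", radius_px = 20), 200L)
  q <- 4 * pi * oracle_poly_area(circ) / oracle_perimeter(circ)^2
  expect_gte(q, 0.99)
  # aspect-5 ellipse: moment eccentricity sqrt(1 - 1/25)
  ell <- make_shape(archetype_params("elongated", radius_px = 20,
                                     aspect_ratio = 5), 200L)
  expect_equal(as.numeric(shape_eccentricity(ell)), sqrt(1 - 1 / 25),
               tolerance = 0.01)
  # 6-lobe star, depth 0.5: solidity well below convex, against hull oracle
  star <- make_shape(archetype_params("protruded", radius_px = 20,
                                      n_protrusions = 6,
                                      protrusion_depth = 0.5), 240L)
  sol <- shape_solidity(star)
  expect_lt(sol, 0.8)
  expect_equal(sol, oracle_poly_area(star) / oracle_hull_area(star),
               tolerance = 1e-6)
})

test_that("shapes are simple closed polygons at default noise", {
  set.seed(2)
  for (p in default_archetypes(c("circular", "protruded", "elongated", "mixed"))) {
    xy <- make_shape(p)
    expect_gte(nrow(xy), 12L)
    expect_gt(macmot:::poly_signed_area(xy), 0)  # CCW
    # star-convex by construction: radii all positive around the centroid
    ctr <- colMeans(xy)
    expect_true(all(sqrt(rowSums(sweep(xy, 2, ctr)^2)) > 0))
  }
})

test_that("degenerate track regimes obey closed forms", {
  straight <- archetype_params("circular", radius_px = 10,
                               mean_step_px = 3, turn_concentration = Inf)
  set.seed(3)
  tr <- make_track(straight, 20L)
  expect_equal(track_persistence(tr), 1, tolerance = 1e-12)
  frozen <- archetype_params("circular", radius_px = 10, mean_step_px = 0)
  tr0 <- make_track(frozen, 10L)
  expect_equal(max(abs(sweep(tr0, 2, tr0[1, ]))), 0)
  expect_equal(track_speed(tr0, 5), 0)
  expect_error(make_track(straight, 1L), "n_frames")
})

test_that("default archetypes reproduce the speed and persistence orderings", {
  arcs <- default_archetypes()
  set.seed(101)
  stats <- sapply(arcs, function(p) {
    sp <- pe <- numeric(300)
    for (i in 1:300) {
      tr <- make_track(p, 37L)
      sp[i] <- track_speed(tr, 5)
      pe[i] <- track_persistence(tr)
    }
    c(speed = mean(sp), pers = mean(pe))
  })
  expect_gt(stats["speed", "protruded"], stats["speed", "elongated"])
  expect_gt(stats["speed", "elongated"], stats["speed", "circular"])
  expect_gt(stats["pers", "elongated"], stats["pers", "circular"])
  expect_gt(stats["pers", "circular"], stats["pers", "protruded"])
})

test_that("render_cohort produces consistent, reproducible stacks", {
  cfg <- synthetic_config("M0", n_cells = 1L, n_frames = 2L,
                          image_size_px = c(128L, 128L), rng_seed = 4L)
  coh <- render_cohort(cfg)
  for (f in coh$stack$frames)
    expect_identical(sort(unique(f[f > 0L])), 1L)
  # determinism: bit-identical stacks from the same config
  coh2 <- render_cohort(cfg)
  expect_identical(coh$stack$frames, coh2$stack$frames)
  expect_identical(coh$tracks, coh2$tracks)
  # mask/track consistency: rendered centroid near ground-truth position
  reg <- extract_regions(coh$stack)
  gt <- coh$tracks
  for (r in reg) {
    g <- gt[gt$frame == r$frame_index, ]
    expect_lt(sqrt((r$centroid[["x"]] - g$x)^2 + (r$centroid[["y"]] - g$y)^2),
              1.5)
  }
})

test_that("an image too small for the population is rejected", {
  expect_error(render_cohort(synthetic_config("M0", n_cells = 50L,
                                              image_size_px = c(96L, 96L))),
               "too small")
})

test_that("mixture sampling matches the requested weights", {
  coh <- macrophage_cohort(n_cells = c(M1 = 400), purity = 0.70,
                           mixed_fraction = 0, seed = 12)
  frac <- mean(coh$archetype == "protruded")
  expect_lt(abs(frac - 0.70), 0.03)
})

test_that("the feature cohort is reproducible and carries all columns", {
  a <- macrophage_cohort(n_cells = c(M0 = 20, M1 = 20, M2 = 20), seed = 9)
  b <- macrophage_cohort(n_cells = c(M0 = 20, M1 = 20, M2 = 20), seed = 9)
  expect_identical(a, b)
  expect_true(all(c("eccentricity", "solidity", "compactness", "cell_size",
                    "speed", "persistence", "hull_area") %in% names(a)))
  expect_true(all(a$persistence >= 0 & a$persistence <= 1))
  expect_true(all(a$speed >= 0))
})
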