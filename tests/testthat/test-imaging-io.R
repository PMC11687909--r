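# Label-stack IO, region extraction, contour extraction, linking and the
# track-duration filter.

test_that("label stacks round-trip through multi-page TIFF", {
  cfg <- synthetic_config("M2", n_cells = 3L, n_frames = 3L,
                          image_size_px = c(320L, 320L), rng_seed = 21L)
  coh <- render_cohort(cfg)
  d <- withr::local_tempdir()
  paths <- write_cohort(coh, d)
  st <- read_label_stack(paths[["stack"]], frame_interval_min = 5)
  expect_length(st$frames, 3L)
  expect_identical(st$frames, coh$stack$frames)
  expect_error(read_label_stack(file.path(d, "nope.tif")), "no such file")
  bad <- file.path(d, "empty.tif")
  file.create(bad)
  expect_error(read_label_stack(bad), "cannot read")
})

test_that("region extraction matches naive pixel counting", {
  # 10x10 filled square: area 100, centroid at the square centre
  img <- matrix(0L, 30L, 30L)
  img[6:15, 11:20] <- 1L
  regs <- extract_regions(label_stack(list(img)))
  expect_length(regs, 1L)
  expect_equal(regs[[1L]]$area_px, 100L)
  expect_equal(unname(regs[[1L]]$centroid), c(15.5, 10.5))
  # two labels -> two regions
  img[25:28, 2:5] <- 2L
  regs <- extract_regions(label_stack(list(img)))
  expect_length(regs, 2L)
  # random blob: area equals a naive scan of the mask
  set.seed(31)
  blob <- matrix(as.integer(matrix(runif(400), 20L) > 0.6), 20L)
  regs <- extract_regions(label_stack(list(blob)))
  expect_equal(sum(vapply(regs, `[[`, 0L, "area_px")), sum(blob == 1L))
})

test_that("binary masks are split into 8-connected components", {
  img <- matrix(0L, 10L, 10L)
  img[2, 2] <- 1L; img[3, 3] <- 1L        # diagonal touch: one component
  img[8, 8] <- 1L                          # far away: second component
  regs <- extract_regions(label_stack(list(img)))
  expect_length(regs, 2L)
  expect_setequal(vapply(regs, `[[`, 0L, "area_px"), c(2L, 1L))
})

test_that("area conservation holds per frame on a rendered stack", {
  coh <- render_cohort(synthetic_config("M1", n_cells = 4L, n_frames = 2L,
                                        image_size_px = c(256L, 256L),
                                        rng_seed = 3L))
  regs <- extract_regions(coh$stack)
  for (f in seq_along(coh$stack$frames)) {
    in_frame <- Filter(function(r) r$frame_index == f, regs)
    expect_equal(sum(vapply(in_frame, `[[`, 0L, "area_px")),
                 sum(coh$stack$frames[[f]] > 0L))
  }
})

test_that("sub-pixel contours reproduce analytic area and perimeter", {
  # disk r = 30: contour area within 1% of pi r^2
  reg <- disk_region(30L)
  ct <- region_to_contour(reg)
  expect_equal(oracle_poly_area(ct), pi * 900, tolerance = 0.01)
  # 20 px square: perimeter within 2.5% of 80 under the smoothing
  # convention (corners are rounded at the sample-spacing scale)
  sq <- square_region(20L)
  ct <- region_to_contour(sq)
  expect_equal(oracle_perimeter(ct), 80, tolerance = 0.025)
  # orientation contract: CCW
  expect_gt(macmot:::poly_signed_area(ct), 0)
  expect_gt(macmot:::poly_signed_area(region_to_contour(disk_region(8L))), 0)
  # single pixel: unit square
  img <- matrix(0L, 5L, 5L); img[3L, 3L] <- 1L
  one <- extract_regions(label_stack(list(img)))[[1L]]
  expect_equal(oracle_poly_area(region_to_contour(one)), 1)
})

test_that("persistent labels are linked by identity", {
  coh <- render_cohort(synthetic_config("M0", n_cells = 3L, n_frames = 5L,
                                        image_size_px = c(256L, 256L),
                                        rng_seed = 8L))
  trks <- link_tracks(extract_regions(coh$stack), parent_label = "M0")
  expect_length(trks, 3L)
  expect_true(all(vapply(trks, function(t) length(t$frames), 0L) == 5L))
  # two stationary cells never swap
  img <- matrix(0L, 40L, 40L)
  img[5:10, 5:10] <- 1L; img[25:30, 25:30] <- 2L
  st <- label_stack(rep(list(img), 4L))
  trk <- link_tracks(extract_regions(st))
  expect_length(trk, 2L)
  for (t in trk)
    expect_equal(max(dist(t$centroids)), 0)
})

test_that("greedy linking recovers ground truth in the sparse regime", {
  coh <- render_cohort(synthetic_config("M2", n_cells = 6L, n_frames = 8L,
                                        image_size_px = c(640L, 640L),
                                        rng_seed = 14L))
  regs <- extract_regions(coh$stack)
  # strip label identity: force the distance-based path
  trks <- link_tracks(regs, method = "distance")
  gt <- coh$tracks
  hits <- 0L; total <- 0L
  for (t in trks) {
    for (i in seq_along(t$frames)) {
      g <- gt[gt$frame == t$frames[i], ]
      d <- sqrt((g$x - t$centroids[i, 1])^2 + (g$y - t$centroids[i, 2])^2)
      # the nearest ground-truth cell must be this track's label
      hits <- hits + (g$cell_id[which.min(d)] == t$regions[[1L]]$label)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("the one-hour duration filter keeps 13-frame tracks and drops 12", {
  mk <- function(n) macmot:::new_cell_track(1L, "M0", seq_len(n),
                                            cbind(seq_len(n), 0),
                                            frame_interval_min = 5)
  trks <- structure(list(mk(13L), mk(12L), mk(37L)), class = "track_list")
  kept <- filter_min_duration(trks, 60)
  expect_length(kept, 2L)
  expect_setequal(vapply(kept, function(t) length(t$frames), 0L), c(13L, 37L))
  expect_length(filter_min_duration(trks, 0), 3L)
  # monotonicity: raising the threshold never increases the count
  counts <- vapply(c(0, 30, 60, 120, 500),
                   function(m) length(filter_min_duration(trks, m)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("track tables round-trip through CSV", {
  df <- data.frame(cell_id = rep(1:2, each = 3), frame = rep(1:3, 2),
                   x = rnorm(6), y = rnorm(6), parent_label = "M1")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  trks <- read_track_table(f, frame_interval_min = 5)
  expect_length(trks, 2L)
  expect_equal(trks[[1L]]$duration_min, 10)
  expect_equal(trks[[2L]]$centroids[, 1L], df$x[4:6])
  expect_error(tracks_from_table(df[, -3L]), "missing")
})
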