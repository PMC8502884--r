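# Synthetic direction fields (no model fitting): a straight tube along z on a
# 20 x 20 x 24 grid of 2.5 mm voxels, metric 1 inside the tube and 0 outside,
# so an FA-style floor at 0.20 confines propagation to the tube.

tube_setup <- function(shape = c(20L, 20L, 24L), radius = 3) {
  vs <- 2.5
  idx <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                               z = 0:(shape[3] - 1)))
  cx <- (shape[1] - 1) / 2
  in_tube <- (idx[, 1] - cx)^2 + (idx[, 2] - cx)^2 <= radius^2
  metric <- image_grid(array(as.numeric(in_tube), shape),
                       voxel_size = rep(vs, 3))
  dirs <- image_grid(array(rep(c(0, 0, 1), each = prod(shape)),
                           c(shape, 3L)), voxel_size = rep(vs, 3))
  seed_mask <- image_grid(array(as.numeric(in_tube & idx[, 3] %in% c(1L, 2L)),
                                shape), voxel_size = rep(vs, 3))
  list(metric = metric, dirs = dirs, seed = seed_mask, in_tube = in_tube,
       shape = shape, vs = vs)
}

test_that("streamlines in a straight tube run cap to cap", {
  tu <- tube_setup()
  rule <- stop_rule(tu$metric, "floor", 0.20, length_bounds_mm = c(30, 300))
  tr <- track(tu$dirs, rule, tu$seed, target_count = 200L, rng_seed = 3L)
  expect_length(tr$streamlines, 200L)
  expect_false(tr$provenance$starved)
  zs <- t(vapply(tr$streamlines, function(s) range(s[, 3]), numeric(2)))
  # endpoints within one voxel of the tube end caps (z = 0 and z = 23 voxels)
  expect_lt(max(zs[, 1]), 1 * tu$vs)
  expect_gt(min(zs[, 2]), 22 * tu$vs)
})

test_that("accepted streamlines satisfy step, angle and length invariants", {
  tu <- tube_setup()
  rule <- stop_rule(tu$metric, "floor", 0.20)
  tr <- track(tu$dirs, rule, tu$seed, target_count = 100L, rng_seed = 4L)
  lens <- streamline_lengths(tr)
  expect_true(all(lens >= 30 & lens <= 300))
  cosmin <- cos(rule$max_angle_deg * pi / 180)
  for (s in tr$streamlines[1:20]) {
    seg <- diff(s)
    d <- sqrt(rowSums(seg^2))
    expect_lt(max(abs(d - 0.5)), 1e-9)
    u <- seg / d
    dots <- rowSums(u[-1, , drop = FALSE] * u[-nrow(u), , drop = FALSE])
    expect_true(all(dots >= cosmin - 1e-12))
  }
})

test_that("tracking is deterministic given the rng seed", {
  tu <- tube_setup()
  rule <- stop_rule(tu$metric, "floor", 0.20)
  a <- track(tu$dirs, rule, tu$seed, target_count = 50L, rng_seed = 7L)
  b <- track(tu$dirs, rule, tu$seed, target_count = 50L, rng_seed = 7L)
  expect_identical(a$streamlines, b$streamlines)
  c2 <- track(tu$dirs, rule, tu$seed, target_count = 50L, rng_seed = 8L)
  expect_false(identical(a$streamlines, c2$streamlines))
})

test_that("a floor above the metric maximum starves immediately", {
  tu <- tube_setup()
  rule <- suppressWarnings(stop_rule(tu$metric, "floor", 1.5))
  tr <- track(tu$dirs, rule, tu$seed, target_count = 10L, rng_seed = 5L,
              max_attempts = 500L)
  expect_length(tr$streamlines, 0L)
  expect_true(tr$provenance$starved)
})

test_that("a ceiling rule terminates streamlines at a high-metric block", {
  tu <- tube_setup()
  # dispersion-like metric: low along the tube, high in a mid-tube block
  odi <- array(0.1, tu$shape)
  odi[, , 11:13] <- 0.8
  odi_grid <- image_grid(odi, voxel_size = rep(tu$vs, 3))
  rule <- stop_rule(odi_grid, "ceiling", 0.45, length_bounds_mm = c(10, 300))
  tr <- track(tu$dirs, rule, tu$seed, target_count = 50L, rng_seed = 6L)
  expect_gt(length(tr$streamlines), 0L)
  zmax <- vapply(tr$streamlines, function(s) max(s[, 3]), numeric(1))
  expect_lt(max(zmax), 11 * tu$vs)   # nothing crosses into the block
})

test_that("ROI filtering applies every inclusion and any exclusion", {
  tu <- tube_setup()
  mk_slab <- function(zrange) {
    a <- array(0, tu$shape)
    a[, , zrange + 1L] <- 1
    image_grid(a, voxel_size = rep(tu$vs, 3))
  }
  inf_cap <- mk_slab(0:1); sup_cap <- mk_slab(22:23); mid <- mk_slab(12L)
  line_z <- function(z0, z1, x = 25) {
    n <- round((z1 - z0) / 0.5)
    unname(cbind(x, 25, z0 + 0.5 * (0:n)))
  }
  full <- line_z(1, 58)        # crosses both caps
  short <- line_z(1, 25)       # misses the superior cap
  tr <- tractogram(list(full, short), step_size_mm = 0.5)
  both <- filter_by_rois(tr, roi_set(include = list(inf_cap, sup_cap)))
  expect_length(both$streamlines, 1L)
  expect_equal(both$streamlines[[1]], full)
  none <- filter_by_rois(tr, roi_set(include = list(inf_cap, sup_cap),
                                     exclude = list(mid)))
  expect_length(none$streamlines, 0L)  # the survivor crosses the exclusion
  expect_error(roi_set(include = list()), "parameter error")
})

test_that("tract voxelization counts visited voxels exactly", {
  grid <- image_grid(array(0, c(12L, 12L, 12L)), voxel_size = c(2.5, 2.5, 2.5))
  expect_equal(sum(tract_mask(tractogram(list(), 0.5), grid)$data), 0)
  # a straight streamline along a grid axis spanning 10 voxel centres
  pts <- cbind(5 * 2.5, 5 * 2.5, seq(2.5, 2.5 + 9 * 2.5, by = 0.5))
  tm <- tract_mask(tractogram(list(pts), 0.5), grid)
  expect_equal(sum(tm$data), 10)
  expect_equal(mask_volume(tm), 10 * 2.5^3)
})

test_that("the quota counts post-filter acceptances when ROIs are supplied", {
  tu <- tube_setup()
  rule <- stop_rule(tu$metric, "floor", 0.20)
  mk_slab <- function(zrange) {
    a <- array(0, tu$shape)
    a[, , zrange + 1L] <- 1
    image_grid(a, voxel_size = rep(tu$vs, 3))
  }
  rois <- roi_set(include = list(mk_slab(0:1), mk_slab(22:23)))
  tr <- track(tu$dirs, rule, tu$seed, target_count = 40L, rng_seed = 9L,
              rois = rois)
  expect_length(tr$streamlines, 40L)
  for (s in tr$streamlines[1:5])
    expect_true(nodditract:::passes_rois(s, rois))
})
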