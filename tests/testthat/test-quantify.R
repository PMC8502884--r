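test_that("condition masks partition the edematous tract set", {
  set.seed(40)
  for (i in 1:10) {
    d <- as_grid(array(rbinom(512, 1, 0.4), c(8L, 8L, 8L)))
    n <- as_grid(array(rbinom(512, 1, 0.4), c(8L, 8L, 8L)))
    e <- as_grid(array(rbinom(512, 1, 0.5), c(8L, 8L, 8L)))
    cm <- condition_masks(d, n, e)
    expect_equal(sum(cm$dn$data * cm$d_only$data), 0)
    expect_equal(sum(cm$dn$data * cm$n_only$data), 0)
    expect_equal(sum(cm$d_only$data * cm$n_only$data), 0)
    un <- pmin(cm$dn$data + cm$d_only$data + cm$n_only$data, 1)
    expect_equal(un, pmin(d$data + n$data, 1) * e$data)
  }
})

test_that("degenerate condition-mask cases behave as specified", {
  m <- as_grid(array(rep(c(1, 0), c(40, 472)), c(8L, 8L, 8L)))
  e <- as_grid(array(1, c(8L, 8L, 8L)))
  cm <- condition_masks(m, m, e)
  expect_equal(sum(cm$d_only$data), 0)
  expect_equal(sum(cm$n_only$data), 0)
  expect_equal(cm$dn$data, m$data)
  d2 <- as_grid(array(rep(c(0, 1, 0), c(40, 40, 432)), c(8L, 8L, 8L)))
  cm2 <- condition_masks(m, d2, e)
  expect_equal(sum(cm2$dn$data), 0)
  empty <- as_grid(array(0, c(8L, 8L, 8L)))
  cm3 <- condition_masks(m, d2, empty)
  expect_equal(sum(cm3$dn$data + cm3$d_only$data + cm3$n_only$data), 0)
})

test_that("PIV is the condition-to-tract volume ratio with guarded edges", {
  expect_equal(piv(50, 200), 0.25)
  expect_equal(piv(0, 123), 0)
  expect_equal(piv(200, 200), 1)
  expect_error(piv(1, 0), "undefined-metric")
  expect_error(piv(10, 5), "validation error")
})

test_that("lesion-to-tract distance matches hand geometry", {
  les <- array(0, c(10L, 10L, 10L)); les[2, 2, 2] <- 1
  cst <- array(0, c(10L, 10L, 10L)); cst[5, 6, 2] <- 1   # offset (3,4,0)
  expect_equal(ltd(as_grid(les), as_grid(cst)), 5)       # 3-4-5 at 1 mm
  # face-adjacent single voxels at 2.5 mm pitch
  les2 <- array(0, c(6L, 6L, 6L)); les2[3, 3, 3] <- 1
  cst2 <- array(0, c(6L, 6L, 6L)); cst2[4, 3, 3] <- 1
  expect_equal(ltd(as_grid(les2, voxel = 2.5), as_grid(cst2, voxel = 2.5)), 2.5)
  # overlap -> 0
  expect_equal(ltd(as_grid(les), as_grid(les)), 0)
  expect_error(ltd(as_grid(les), as_grid(array(0, c(10L, 10L, 10L)))),
               "parameter error")
})

test_that("lesion-to-tract distance equals the all-pairs brute-force scan", {
  set.seed(41)
  for (i in 1:8) {
    shape <- c(12L, 14L, 10L)
    les <- array(0, shape)
    cst <- array(0, shape)
    les[sample(prod(shape), 30)] <- 1
    cst[sample(prod(shape), 30)] <- 1
    vs <- sample(c(1, 2, 2.5), 1)
    got <- ltd(as_grid(les, voxel = vs), as_grid(cst, voxel = vs))
    want <- if (any(les & cst)) 0 else oracle_ltd_bruteforce(les, cst, vs)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("distance weighting divides by LTD and flags contact", {
  w <- weighted_indices(100, 0.25, 5)
  expect_equal(w$volume_ltd, 20)
  expect_equal(w$piv_ltd, 0.05)
  expect_false(w$undefined)
  expect_equal(weighted_indices(100, 0.25, 4)$volume_ltd, 25)
  w0 <- weighted_indices(100, 0.25, 0)
  expect_true(w0$undefined)
  expect_true(is.na(w0$piv_ltd))
})

test_that("fraction summaries average the absolute fractions and sum to 1", {
  shape <- c(4L, 4L, 4L)
  fit <- list(
    vf_ic = as_grid(array(0.2, shape)), vf_ec = as_grid(array(0.5, shape)),
    vf_iso = as_grid(array(0.3, shape)), fitted = array(TRUE, shape))
  class(fit) <- "noddi_fit"
  fs <- fraction_summary(fit, array(1, shape))
  expect_equal(unname(fs), c(0.2, 0.5, 0.3))
  # two-voxel mask with differing iso fractions
  fit$vf_iso$data[1, 1, 1] <- 0.2; fit$vf_ic$data[1, 1, 1] <- 0.3
  fit$vf_iso$data[2, 1, 1] <- 0.4; fit$vf_ic$data[2, 1, 1] <- 0.1
  m <- array(0, shape); m[1:2, 1, 1] <- 1
  fs2 <- fraction_summary(fit, m)
  expect_equal(unname(fs2["vf_iso"]), 0.3)
  expect_equal(sum(fs2), 1, tolerance = 1e-9)
  expect_error(fraction_summary(fit, array(0, shape)), "parameter error")
})
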