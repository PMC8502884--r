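test_that("the two-shell protocol has the right composition and unit directions", {
  sch <- make_protocol(seed = 5L)
  expect_length(sch$bvals, 94L)
  expect_equal(as.integer(table(sch$bvals)), c(4L, 30L, 60L))
  dwi <- sch$bvals > 0
  expect_equal(sqrt(rowSums(sch$bvecs[dwi, ]^2)), rep(1, sum(dwi)),
               tolerance = 1e-10)
  # near-uniform coverage: no two directions (mod antipode) closer than a few
  # degrees on the 60-direction shell
  g2 <- sch$bvecs[sch$bvals == 2000, ]
  cosang <- abs(tcrossprod(g2))
  diag(cosang) <- 0
  expect_lt(max(cosang), cos(10 * pi / 180))
  expect_identical(make_protocol(seed = 5L), sch)      # determinism
  expect_false(isTRUE(all.equal(make_protocol(seed = 6L)$bvecs, sch$bvecs)))
})

test_that("phantom ground truth is laid out as specified", {
  spec <- phantom_spec()
  gt <- build_phantom(spec)
  lab <- gt$label
  expect_true(all(gt$viso[lab == "edematous-bundle"] == spec$edema_viso))
  expect_true(all(gt$viso[lab == "bundle"] == spec$bundle_viso))
  # straight tube: orientation equals the tube tangent (0,0,1)
  mu <- matrix(gt$mu, ncol = 3L)
  fib <- as.vector(lab) %in% c("bundle", "edematous-bundle")
  expect_equal(mu[fib, ], matrix(rep(c(0, 0, 1), each = sum(fib)), ncol = 3L))
  # lesion disjoint from the bundle, edema overlapping it
  expect_equal(sum(gt$lesion$data * gt$bundle$data), 0)
  expect_gt(sum(gt$edema$data * gt$bundle$data), 0)
  # edema voxels have strictly higher free water than non-edematous bundle
  expect_gt(min(gt$viso[lab == "edematous-bundle"]),
            max(gt$viso[lab == "bundle"]))
  for (m in c(gt$include, gt$exclude))
    expect_true(all(m$data %in% c(0, 1)))
})

test_that("a curved bundle's orientation follows the local tangent", {
  gt <- build_phantom(phantom_spec(bundle_bend_vox = 4))
  lab <- as.vector(gt$label)
  mu <- matrix(gt$mu, ncol = 3L)[lab %in% c("bundle", "edematous-bundle"), ]
  expect_equal(sqrt(rowSums(mu^2)), rep(1, nrow(mu)), tolerance = 1e-12)
  expect_gt(max(abs(mu[, 1])), 0.05)   # bend shows up in the x component
  expect_equal(mu[, 2], rep(0, nrow(mu)))
})

test_that("noise-free signals follow the forward model closed forms", {
  sch <- make_protocol(seed = 5L)
  gt <- build_phantom(phantom_spec(grid_shape = c(16L, 16L, 20L)))
  dwi <- simulate_dwi(gt, sch, snr = Inf)
  csf <- which(gt$label == "csf", arr.ind = TRUE)[1, ]
  sig <- dwi$data[csf[1], csf[2], csf[3], ]
  expect_equal(sig[sch$bvals == 0], rep(1, 4))
  expect_equal(sig[sch$bvals == 1000], rep(exp(-3), 30), tolerance = 1e-12)
  expect_equal(sig[sch$bvals == 2000], rep(exp(-6), 30 * 2), tolerance = 1e-12)
  tissue <- as.vector(gt$label != "background")
  sigs <- matrix(dwi$data, ncol = 94)[tissue, ]
  expect_true(all(sigs > 0 & sigs <= 1))
})

test_that("Rician noise is seeded, reproducible and positively biased", {
  sch <- make_protocol(seed = 5L)
  gt <- build_phantom(phantom_spec(grid_shape = c(16L, 16L, 20L)))
  a <- simulate_dwi(gt, sch, snr = 30, rng_seed = 9L)
  b <- simulate_dwi(gt, sch, snr = 30, rng_seed = 9L)
  expect_identical(a$data, b$data)
  c2 <- simulate_dwi(gt, sch, snr = 30, rng_seed = 10L)
  expect_false(identical(a$data, c2$data))
  # Rician bias: mean noisy b=0 over >= 1e3 tissue voxels exceeds the
  # noise-free value (1) at snr 10
  noisy <- simulate_dwi(gt, sch, snr = 10, rng_seed = 11L)
  tissue <- which(as.vector(gt$label != "background"))
  expect_gt(length(tissue), 1000L)
  b0mean <- rowMeans(matrix(noisy$data, ncol = 94)[tissue, sch$bvals == 0])
  expect_gt(mean(b0mean), 1)
  expect_error(simulate_dwi(gt, sch, snr = 0), "parameter error")
})
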