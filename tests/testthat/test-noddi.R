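single_voxel_dwi <- function(params, scheme) {
  sig <- noddi_signal(params, scheme)
  image_grid(array(sig, c(1, 1, 1, length(sig))), voxel_size = c(2.5, 2.5, 2.5))
}

test_that("the dispersion index maps concentration as (2/pi) atan(1/kappa)", {
  expect_equal(odi_from_kappa(1), 0.5)
  expect_equal(odi_from_kappa(0.01), (2 / pi) * atan(100))
  expect_lt(odi_from_kappa(1e8), 1e-7)
  expect_error(odi_from_kappa(0), "domain error")
  expect_error(odi_from_kappa(-1), "domain error")
  # strictly decreasing, inverse consistent
  ks <- c(0.05, 0.3, 1, 4, 16, 64)
  expect_true(all(diff(odi_from_kappa(ks)) < 0))
  expect_equal(kappa_from_odi(odi_from_kappa(ks)), ks, tolerance = 1e-10)
})

test_that("forward signal reproduces its closed-form limits", {
  sch <- make_protocol(seed = 5L)
  # pure free water
  s <- noddi_signal(noddi_params(1, 0.5, 1, c(0, 0, 1)), sch)
  expect_equal(s[sch$bvals == 0], rep(1, 4))
  expect_equal(unique(round(s[sch$bvals == 1000], 12)), round(exp(-3), 12))
  # perfectly coherent stick perpendicular to the gradient: no attenuation
  perp <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(noddi_signal(noddi_params(0, 1, Inf, c(0, 0, 1)), perp)[2], 1,
               tolerance = 1e-9)
  # coherent stick parallel: full parallel-diffusivity attenuation
  par <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(noddi_signal(noddi_params(0, 1, Inf, c(0, 0, 1)), par)[2],
               exp(-1.7), tolerance = 1e-9)
})

test_that("the Watson average agrees with dense spherical quadrature", {
  ns <- asNamespace("nodditract")
  for (kappa in c(0.1, 1, 4, 16, 64)) {
    pl <- ns$watson_moments(kappa)
    for (b in c(1000, 2000)) {
      x <- b * D_PAR
      cl <- ns$watson_signal_coeffs(x)
      for (ct in c(0, 0.25, 0.6, 0.95, 1)) {
        Pl <- ns$legendre_table(ct, 24L)[, seq(1, 25, 2), drop = FALSE]
        mine <- sum(cl * pl * Pl)
        oracle <- ns$watson_average_bruteforce(x, kappa, ct)
        expect_lt(abs(mine - oracle) / abs(oracle), 1e-6)
      }
    }
  }
})

test_that("the compiled objective matches the R forward model", {
  ns <- asNamespace("nodditract")
  sch <- make_protocol(seed = 5L)
  pre <- ns$noddi_precompute(sch)
  set.seed(20)
  for (i in 1:20) {
    viso <- runif(1); vic <- runif(1); kappa <- runif(1, 0.02, 60)
    mu <- rnorm(3); mu <- mu / sqrt(sum(mu^2))
    y <- runif(94)
    r_sse <- sum((y - ns$noddi_signal_fast(viso, vic, kappa, mu, pre))^2)
    th <- acos(mu[3]); ph <- atan2(mu[2], mu[1])
    c_sse <- ns$.noddi_sse(c(qlogis(viso), qlogis(vic), log(kappa), th, ph),
                           y, pre)
    expect_equal(c_sse, r_sse, tolerance = 1e-10)
  }
})

test_that("noise-free parameter recovery is within +/- 0.02", {
  sch <- make_protocol(seed = 5L)
  cases <- list(c(0.05, 0.6, 16), c(0.3, 0.4, 4), c(0.9, 0.6, 16),
                c(0.1, 0.8, 1))
  for (cs in cases) {
    p <- noddi_params(cs[1], cs[2], cs[3], c(0.2, -0.1, 0.97))
    f <- fit_noddi(single_voxel_dwi(p, sch), sch, array(1, c(1, 1, 1)),
                   init_mu = array(c(0, 0, 1), c(1, 1, 1, 3)))
    expect_lt(abs(f$viso$data[1] - cs[1]), 0.02)
    expect_lt(abs(f$vic$data[1] - cs[2]), 0.02)
    expect_lt(abs(f$odi$data[1] - odi_from_kappa(cs[3])), 0.02)
    ang <- acos(min(1, abs(sum(matrix(f$mu$data, ncol = 3) * p$mu))))
    expect_lt(ang * 180 / pi, 3)
  }
  # pure free water: viso recovered at the boundary
  f <- fit_noddi(single_voxel_dwi(noddi_params(1, 0, 1, c(0, 0, 1)), sch),
                 sch, array(1, c(1, 1, 1)),
                 init_mu = array(c(0, 0, 1), c(1, 1, 1, 3)))
  expect_gte(f$viso$data[1], 0.99)
})

test_that("absolute volume fractions sum to one at every fitted voxel", {
  sch <- make_protocol(seed = 5L)
  set.seed(21)
  dat <- array(0, c(3, 1, 1, 94))
  for (i in 1:3) {
    p <- noddi_params(runif(1), runif(1), runif(1, 0.1, 30),
                      rnorm(3) + c(0, 0, 1))
    dat[i, 1, 1, ] <- noddi_signal(p, sch) *
      (1 + 0.02 * rnorm(94))             # mild noise: identity is algebraic
  }
  dwi <- image_grid(dat, voxel_size = c(2.5, 2.5, 2.5))
  f <- fit_noddi(dwi, sch, array(1, c(3, 1, 1)),
                 init_mu = array(rep(c(0, 0, 1), each = 3), c(3, 1, 1, 3)))
  s <- f$vf_ic$data + f$vf_ec$data + f$vf_iso$data
  expect_lt(max(abs(s[f$fitted] - 1)), 1e-10)
})

test_that("fitted ODI decreases along a ground-truth concentration ladder", {
  sch <- make_protocol(seed = 5L)
  odis <- vapply(c(0.5, 2, 8, 32), function(k) {
    f <- fit_noddi(single_voxel_dwi(noddi_params(0.1, 0.5, k, c(0, 0, 1)), sch),
                   sch, array(1, c(1, 1, 1)),
                   init_mu = array(c(0, 0, 1), c(1, 1, 1, 3)))
    f$odi$data[1]
  }, numeric(1))
  expect_true(all(diff(odis) < 0))
})

test_that("voxels without usable b0 signal are flagged unfitted", {
  sch <- make_protocol(seed = 5L)
  dwi <- image_grid(array(0, c(1, 1, 1, 94)), voxel_size = c(2.5, 2.5, 2.5))
  f <- fit_noddi(dwi, sch, array(1, c(1, 1, 1)),
                 init_mu = array(c(0, 0, 1), c(1, 1, 1, 3)))
  expect_false(f$fitted[1, 1, 1])
  expect_true(is.na(f$odi$data[1]))
})
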