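# Synthetic multi-shell DWI phantom: a corticospinal-tract-like bundle running
# inferior -> superior through a block of vasogenic edema, with known
# per-voxel ground truth, so every downstream stage (tensor fit, NODDI fit,
# tracking, calibration, quantification) is testable without patient data.

#' Two-shell acquisition protocol
#'
#' 94 volumes: `n_b0` null images, `n_b1000` directions at b = 1000 s/mm^2 and
#' `n_b2000` at b = 2000 s/mm^2, with near-uniform antipodally symmetric
#' spherical coverage from seeded electrostatic repulsion (the acquisition's
#' own gradient tables are not published, so the set is generated).
#'
#' @param n_b0,n_b1000,n_b2000 shell sizes
#' @param seed RNG seed for the repulsion initialization
#' @return a [gradient_scheme()] of length `n_b0 + n_b1000 + n_b2000`
#' @export
make_protocol <- function(n_b0 = 4L, n_b1000 = 30L, n_b2000 = 60L, seed = 1L) {
  dirs1 <- repulsion_directions(n_b1000, seed = seed)
  dirs2 <- repulsion_directions(n_b2000, seed = seed + 1L)
  gradient_scheme(
    c(rep(0, n_b0), rep(1000, n_b1000), rep(2000, n_b2000)),
    rbind(matrix(0, n_b0, 3L), dirs1, dirs2))
}

# Electrostatic repulsion with antipodal symmetry: gradient descent on the
# Coulomb energy of the n points and their antipodes, renormalizing each step.
repulsion_directions <- function(n, seed = 1L, n_iter = 400L, lr = 0.005) {
  rng <- local_rng(seed)
  x <- matrix(rng$norm(3L * n), n, 3L)
  x <- x / sqrt(rowSums(x^2))
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3L)
    for (sgn in c(1, -1)) {
      for (i in seq_len(n)) {
        d <- x[i, ] - sgn * t(x[-i, , drop = FALSE])  # 3 x (n-1)
        r2 <- colSums(d^2)
        force[i, ] <- force[i, ] + rowSums(sweep(d, 2L, r2^1.5, `/`))
      }
    }
    x <- x + lr * force
    x <- x / sqrt(rowSums(x^2))
  }
  # canonical hemisphere for reproducible signs
  flip <- x[, 3L] < 0 | (x[, 3L] == 0 & x[, 1L] < 0)
  x[flip, ] <- -x[flip, ]
  x
}

#' Phantom specification
#'
#' Geometry and tissue parameters of the synthetic bundle-plus-edema volume.
#' Defaults define the package's reference study conditions: a 40^3 grid of
#' 2.5 mm voxels, a straight tube of radius 3 voxels along z spanning nearly
#' the whole grid, an edema block intersecting its middle, a lesion abutting
#' the edema laterally, axial inclusion caps at both tube ends and lateral
#' exclusion slabs. `edema_viso = 0.9` puts the tensor FA of edematous bundle
#' voxels below the standard 0.20 tracking floor while the Watson orientation
#' stays well defined (see the methods vignette for the arithmetic).
#'
#' @param grid_shape integer 3-vector of voxel counts
#' @param voxel_size_mm isotropic voxel edge, mm
#' @param bundle_radius_vox tube radius in voxels
#' @param bundle_bend_vox lateral displacement amplitude (voxels) of a gentle
#'   half-sine bend in x along the tube; 0 = straight
#' @param edema_viso isotropic (free water) fraction inside the edema block
#' @param edema_mild_viso when non-`NA`, the half of the edema block with
#'   y below the tube axis gets this milder free-water level instead (a graded
#'   edema for exercising the both-trackers-pass / only-NODDI-passes contrast)
#' @param bundle_kappa,bundle_vic,bundle_viso tissue parameters of the bundle
#' @param background_kappa,background_vic,background_viso dispersed gray-like
#'   tissue filling the rest of the brain region
#' @param snr scalar S0-to-noise-sigma ratio used by [simulate_dwi()] defaults
#' @param rng_seed integer seed controlling protocol and noise
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L), voxel_size_mm = 2.5,
                         bundle_radius_vox = 3, bundle_bend_vox = 0,
                         edema_viso = 0.9, edema_mild_viso = NA_real_,
                         bundle_kappa = 16, bundle_vic = 0.6,
                         bundle_viso = 0.05,
                         background_kappa = 0.5, background_vic = 0.4,
                         background_viso = 0.1,
                         snr = 30, rng_seed = 42L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            voxel_size_mm > 0, bundle_radius_vox > 0, snr > 0,
            edema_viso >= 0, edema_viso <= 1)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Build the phantom ground truth
#'
#' Lays out tissue labels and per-voxel Watson-NODDI parameters. Bundle voxels
#' get low dispersion and low free water; edematous bundle voxels keep the
#' bundle orientation and concentration but raised `viso`; the non-bundle part
#' of the edema block keeps the elevated `viso` with dispersed background
#' tissue; a CSF block is pure free water; the lesion abuts the edema block.
#'
#' @param spec a [phantom_spec()]
#' @return object of class `phantom_truth` with fields `viso`, `vic`, `kappa`
#'   (3D arrays), `mu` (X x Y x Z x 3 unit tangents where tissue is oriented),
#'   `label` (character array: bundle / edematous-bundle / edema / gray / csf /
#'   lesion / background), masks `lesion`, `edema`, `analysis` and ROI masks
#'   `include` (inferior cap, superior cap), `exclude` (two lateral slabs), all
#'   [image_grid()]s, plus the originating `spec`
#' @export
build_phantom <- function(spec) {
  shp <- as.integer(spec$grid_shape)
  vs <- spec$voxel_size_mm
  affine <- diag(c(vs, vs, vs, 1))
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  idx <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1), z = 0:(nz - 1)))

  z0 <- 2L; z1 <- nz - 3L            # tube spans z in [z0, z1]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  # gentle half-sine bend in x along z (0 at both ends)
  bend <- function(z) spec$bundle_bend_vox * sin(pi * (z - z0) / (z1 - z0))
  dxc <- idx[, 1] - (cx + bend(idx[, 3]))
  dyc <- idx[, 2] - cy
  in_tube <- (dxc^2 + dyc^2) <= spec$bundle_radius_vox^2 &
    idx[, 3] >= z0 & idx[, 3] <= z1

  # brain region: everything but a 2-voxel air rim
  brain <- idx[, 1] >= 2 & idx[, 1] <= nx - 3 &
    idx[, 2] >= 2 & idx[, 2] <= ny - 3 &
    idx[, 3] >= z0 & idx[, 3] <= z1

  zm0 <- floor(nz * 0.4); zm1 <- floor(nz * 0.6)       # edema z-band
  half <- floor(nx * 0.35)
  edema_block <- idx[, 1] >= floor(nx * 0.32) & idx[, 1] <= floor(nx * 0.67) &
    idx[, 2] >= floor(ny * 0.32) & idx[, 2] <= floor(ny * 0.67) &
    idx[, 3] >= zm0 & idx[, 3] <= zm1
  if (!any(edema_block & in_tube))
    stop("spec error: edema block does not overlap the bundle", call. = FALSE)

  lx0 <- floor(nx * 0.67) + 1L; lx1 <- min(nx - 3L, lx0 + 5L)  # abuts edema
  lesion <- idx[, 1] >= lx0 & idx[, 1] <= lx1 &
    idx[, 2] >= floor(ny * 0.40) & idx[, 2] <= floor(ny * 0.60) &
    idx[, 3] >= zm0 + 1 & idx[, 3] <= zm1 - 1

  csf <- idx[, 1] >= 4 & idx[, 1] <= 7 & idx[, 2] >= 4 & idx[, 2] <= 7 &
    idx[, 3] >= floor(nz * 0.25) & idx[, 3] <= floor(nz * 0.75)

  cap_inf <- idx[, 3] %in% c(z0, z0 + 1L) & brain
  cap_sup <- idx[, 3] %in% c(z1 - 1L, z1) & brain
  excl_left <- idx[, 1] <= 0L
  excl_right <- idx[, 1] >= nx - 1L

  label <- rep("background", nrow(idx))
  label[brain] <- "gray"
  label[csf] <- "csf"
  label[edema_block & brain] <- "edema"
  label[lesion & brain] <- "lesion"
  label[in_tube] <- "bundle"
  label[in_tube & edema_block] <- "edematous-bundle"

  viso <- rep(NA_real_, nrow(idx))
  vic <- rep(NA_real_, nrow(idx))
  kappa <- rep(NA_real_, nrow(idx))
  set_par <- function(lab, vi, vc, ka) {
    sel <- label == lab
    viso[sel] <<- vi; vic[sel] <<- vc; kappa[sel] <<- ka
  }
  set_par("gray", spec$background_viso, spec$background_vic, spec$background_kappa)
  set_par("csf", 1, 0, spec$background_kappa)
  set_par("lesion", 0.3, 0.3, 0.3)
  set_par("bundle", spec$bundle_viso, spec$bundle_vic, spec$bundle_kappa)
  set_par("edema", spec$edema_viso, spec$background_vic, spec$background_kappa)
  set_par("edematous-bundle", spec$edema_viso, spec$bundle_vic, spec$bundle_kappa)
  if (!is.na(spec$edema_mild_viso)) {
    mild <- label %in% c("edema", "edematous-bundle") & idx[, 2] < cy
    viso[mild] <- spec$edema_mild_viso
  }

  # orientation: local tube tangent (d bend/dz, 0, 1) normalized, everywhere
  # oriented tissue exists; meaningless elsewhere
  dbend <- spec$bundle_bend_vox * pi / (z1 - z0) * cos(pi * (idx[, 3] - z0) / (z1 - z0))
  tx <- dbend; tz <- rep(1, nrow(idx))
  tn <- sqrt(tx^2 + tz^2)
  mux <- tx / tn; muy <- rep(0, nrow(idx)); muz <- tz / tn
  no_fiber <- !(label %in% c("bundle", "edematous-bundle"))
  mux[no_fiber] <- 0; muy[no_fiber] <- 0; muz[no_fiber] <- 1

  arr3 <- function(x) array(x, dim = shp)
  grid3 <- function(x) image_grid(arr3(as.numeric(x)), affine = affine)
  tube_or_roi <- in_tube | (edema_block & brain) | lesion | csf
  analysis <- dilate6(arr3(tube_or_roi)) & arr3(brain)

  structure(list(
    spec = spec,
    viso = arr3(viso), vic = arr3(vic), kappa = arr3(kappa),
    mu = array(c(mux, muy, muz), dim = c(shp, 3L)),
    label = arr3(label),
    lesion = grid3(lesion), edema = grid3(edema_block & brain),
    bundle = grid3(in_tube), brain = grid3(brain),
    analysis = image_grid(array(as.numeric(analysis), dim = shp), affine = affine),
    include = list(inferior = grid3(cap_inf), superior = grid3(cap_sup)),
    exclude = list(left = grid3(excl_left), right = grid3(excl_right)),
    affine = affine), class = "phantom_truth")
}

# 6-connected binary dilation (one step)
dilate6 <- function(m) {
  d <- dim(m)
  out <- m > 0
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    a[src[[1]], src[[2]], src[[3]]]
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | shift(m > 0, ax, by)
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  tb <- table(x$label)
  cat("<phantom_truth>", paste(dim(x$viso), collapse = " x "), "voxels:\n ")
  cat(paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate the multi-shell DWI signal of a phantom
#'
#' Noise-free signals come from the Watson-NODDI forward model with S0 = 1;
#' Rician noise (magnitude of a complex Gaussian perturbation, the magnitude-
#' MRI noise model) with `sigma = 1/snr` is then applied. Background (air)
#' voxels carry pure noise.
#'
#' @param gt a `phantom_truth` from [build_phantom()]
#' @param scheme a [gradient_scheme()]
#' @param snr S0-to-sigma ratio; `Inf` disables noise
#' @param rng_seed integer seed for the noise
#' @return 4D [image_grid()] of signals
#' @export
simulate_dwi <- function(gt, scheme, snr = gt$spec$snr, rng_seed = gt$spec$rng_seed) {
  if (snr <= 0) stop("parameter error: snr must be positive", call. = FALSE)
  shp <- dim(gt$viso)
  nvox <- prod(shp)
  nfr <- length(scheme$bvals)
  pre <- noddi_precompute(scheme)
  sig <- matrix(0, nvox, nfr)

  lab <- as.vector(gt$label)
  viso <- as.vector(gt$viso); vic <- as.vector(gt$vic); kap <- as.vector(gt$kappa)
  mu <- matrix(gt$mu, nrow = nvox)
  tissue <- lab != "background"
  # voxels sharing (viso, vic, kappa, mu) share a signal row: group them
  key <- paste(viso, vic, kap, mu[, 1], mu[, 2], mu[, 3])
  key[!tissue] <- NA
  groups <- split(which(tissue), key[tissue])
  for (g in groups) {
    v <- g[1]
    sig[g, ] <- matrix(noddi_signal_fast(viso[v], vic[v], kap[v], mu[v, ], pre),
                       length(g), nfr, byrow = TRUE)
  }
  if (is.finite(snr)) {
    rng <- local_rng(rng_seed)
    sigma <- 1 / snr
    n1 <- matrix(rng$norm(nvox * nfr), nvox, nfr)
    n2 <- matrix(rng$norm(nvox * nfr), nvox, nfr)
    sig <- sqrt((sig + sigma * n1)^2 + (sigma * n2)^2)
  }
  image_grid(array(sig, dim = c(shp, nfr)), affine = gt$affine)
}

# Seeded RNG that does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  draw <- function(fun, n) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, globalenv())
    x <- fun(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    x
  }
  list(norm = function(n) draw(stats::rnorm, n),
       unif = function(n) draw(stats::runif, n))
}
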