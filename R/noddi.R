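# Three-compartment Watson-NODDI model.
#
# Normalized signal at (b, g):
#   A = (1 - viso) * [ vic * A_ic + (1 - vic) * A_ec ] + viso * exp(-b d_iso)
#   A_ic = Watson-average over sticks of exp(-b d_par (g.n)^2)   (see watson.R)
#   A_ec = exp(-b g' D_ec g), D_ec the dispersion-averaged tensor with
#          parallel diffusivity d_par and tortuosity-scaled perpendicular
#          diffusivity d_par (1 - vic):
#            g' D_ec g = d_perp + (d_par - d_perp) (tau c^2 + (1-tau)(1-c^2)/2)
#          with c = g.mu and tau = <(mu.n)^2> under Watson(kappa).
# Fixed diffusivities (standard in-vivo values): d_par = 1.7e-3 mm^2/s,
# d_iso = 3.0e-3 mm^2/s.

#' @export
D_PAR <- 1.7e-3
#' @export
D_ISO <- 3.0e-3

#' Watson-NODDI parameter set for one voxel
#'
#' @param viso isotropic (free water) volume fraction, in `[0, 1]`
#' @param vic intracellular fraction *of the tissue compartment*, in `[0, 1]`
#' @param kappa Watson concentration, > 0 (Inf = perfectly coherent)
#' @param mu orientation 3-vector (normalized internally)
#' @return object of class `noddi_params`
#' @export
noddi_params <- function(viso, vic, kappa, mu) {
  stopifnot(viso >= 0, viso <= 1, vic >= 0, vic <= 1, kappa > 0)
  mu <- as.numeric(mu)
  n <- sqrt(sum(mu^2))
  if (n < 1e-12) stop("validation error: mu must be a nonzero vector", call. = FALSE)
  structure(list(viso = viso, vic = vic, kappa = kappa, mu = mu / n),
            class = "noddi_params")
}

#' Noise-free Watson-NODDI signal for a gradient scheme
#'
#' @param params a [noddi_params()]
#' @param scheme a [gradient_scheme()]
#' @return numeric vector of normalized signals, one per scheme entry
#'   (identically 1 at b = 0)
#' @examples
#' sch <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
#' noddi_signal(noddi_params(1, 0.5, 1, c(0, 0, 1)), sch)[2]  # exp(-3)
#' @export
noddi_signal <- function(params, scheme) {
  pre <- noddi_precompute(scheme)
  noddi_signal_fast(params$viso, params$vic, params$kappa, params$mu, pre)
}

# Per-scheme precomputation shared across voxels: unique shells, the Legendre
# signal coefficients c_l(x) per shell (also expanded per frame for the
# compiled objective), the isotropic attenuations, and the moment-quadrature
# tables.
noddi_precompute <- function(scheme) {
  b <- scheme$bvals
  ub <- sort(unique(b))
  cl <- lapply(ub, function(bb) watson_signal_coeffs(bb * D_PAR))
  q <- watson_quad()
  list(b = b, g = scheme$bvecs, ub = ub,
       shell = match(b, ub),
       cl = cl,
       clmat = vapply(match(b, ub), function(i) cl[[i]],
                      numeric(length(cl[[1]]))),
       iso = exp(-b * D_ISO),
       b0int = as.integer(b == 0),
       qt = q$x, qw = q$w, qP = q$P[, q$even, drop = FALSE])
}

noddi_signal_fast <- function(viso, vic, kappa, mu, pre) {
  mu <- mu / sqrt(sum(mu^2))
  c_ <- as.numeric(pre$g %*% mu)           # g . mu per frame
  P <- legendre_table(c_, WATSON_LMAX)[, seq(1L, WATSON_LMAX + 1L, by = 2L),
                                       drop = FALSE]
  p_l <- watson_moments(kappa)
  tau <- (2 * p_l[2L] + 1) / 3
  # A_ic: per frame, sum_l c_l(shell) p_l P_l(c)
  coef <- vapply(pre$cl, function(cl) cl * p_l, numeric(length(p_l)))
  a_ic <- rowSums(P * t(coef[, pre$shell, drop = FALSE]))
  d_perp <- D_PAR * (1 - vic)
  dd <- D_PAR - d_perp
  d_eff <- d_perp + dd * (tau * c_^2 + (1 - tau) * (1 - c_^2) / 2)
  a_ec <- exp(-pre$b * d_eff)
  sig <- (1 - viso) * (vic * a_ic + (1 - vic) * a_ec) + viso * pre$iso
  sig[pre$b == 0] <- 1
  sig
}

#' Fit the Watson-NODDI model voxelwise
#'
#' Per masked voxel the signal is normalized by the mean b = 0 frame, a coarse
#' grid search over (viso, vic, kappa) is run with the orientation held at its
#' initial value, and all five free parameters are then refined by Nelder-Mead
#' on transformed coordinates (logit fractions, log kappa clamped to
#' `[0.01, 64]`, spherical angles for the orientation). Voxels are independent;
#' results do not depend on evaluation order.
#'
#' @param dwi 4D [image_grid()]
#' @param scheme matching [gradient_scheme()] (two shells plus b = 0 frames)
#' @param mask binary mask ([image_grid()] or array) of voxels to fit
#' @param init_mu optional X x Y x Z x 3 array of initial orientations
#'   (typically the DTI principal eigenvector). When absent a tensor fit on the
#'   b < 1500 sub-scheme supplies it.
#' @param maxit Nelder-Mead iteration cap per voxel
#' @param verbose print progress every few hundred voxels
#' @return object of class `noddi_fit`: scalar maps `viso`, `vic`, `kappa`,
#'   `odi`, `residual` ([image_grid()]), orientation map `mu` (4D), absolute
#'   fraction maps `vf_ic`, `vf_ec`, `vf_iso` with
#'   `VF_ic + VF_ec + VF_iso = 1` at every fitted voxel, and logical
#'   `fitted`/`converged` arrays
#' @export
fit_noddi <- function(dwi, scheme, mask, init_mu = NULL, maxit = 500L,
                      verbose = FALSE) {
  stopifnot(length(dim(dwi$data)) == 4L)
  if (dim(dwi$data)[4L] != length(scheme$bvals))
    stop("format error: frame count does not match scheme length", call. = FALSE)
  m <- as_mask_array(mask, if (inherits(mask, "image_grid")) dwi else NULL)
  shp <- grid_shape(dwi)
  if (is.null(init_mu)) {
    tf <- fit_dti(dwi, scheme, mask = m)
    init_mu <- tf$e1$data
  }

  pre <- noddi_precompute(scheme)
  b0 <- pre$b == 0
  nframe <- length(pre$b)
  grid_viso <- seq(0, 1, by = 0.1)
  grid_vic <- seq(0, 1, by = 0.1)
  grid_kappa <- c(0.25, 1, 4, 16)

  vox <- which(m)
  n <- length(vox)
  nvox <- prod(shp)
  out <- list(viso = rep(NA_real_, nvox), vic = rep(NA_real_, nvox),
              kappa = rep(NA_real_, nvox), residual = rep(NA_real_, nvox),
              mux = rep(NA_real_, nvox), muy = rep(NA_real_, nvox),
              muz = rep(NA_real_, nvox),
              fitted = rep(FALSE, nvox), converged = rep(FALSE, nvox))
  dat <- matrix(dwi$data, nrow = nvox)
  mu0mat <- matrix(init_mu, nrow = nvox)

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (ii in seq_len(n)) {
    v <- vox[ii]
    S <- dat[v, ]
    s0 <- mean(S[b0])
    if (!is.finite(s0) || s0 <= 0) next
    y <- S / s0
    mu0 <- mu0mat[v, ]
    if (!all(is.finite(mu0)) || sum(mu0^2) < 1e-12) mu0 <- c(0, 0, 1)
    mu0 <- mu0 / sqrt(sum(mu0^2))

    # --- grid search (compiled), orientation fixed at mu0 ---
    gres <- .noddi_grid(y, mu0, pre, grid_viso, grid_vic, grid_kappa)
    best <- list(viso = gres[1L], vic = gres[2L], kappa = gres[3L],
                 sse = gres[4L])

    # --- Nelder-Mead refinement over all five free parameters ---
    th0 <- acos(clamp(mu0[3L], -1, 1))
    ph0 <- atan2(mu0[2L], mu0[1L])
    par0 <- c(stats::qlogis(clamp(best$viso, 1e-3, 1 - 1e-3)),
              stats::qlogis(clamp(best$vic, 1e-3, 1 - 1e-3)),
              log(clamp(best$kappa, 0.01, 64)), th0, ph0)
    opt <- stats::optim(par0, .noddi_sse, y = y, pre = pre,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    use_grid <- opt$value > best$sse  # keep grid optimum on failed refinement
    if (use_grid) {
      viso <- best$viso; vic <- best$vic; kappa <- best$kappa; mu <- mu0
      res <- best$sse
    } else {
      viso <- stats::plogis(opt$par[1L]); vic <- stats::plogis(opt$par[2L])
      kappa <- clamp(exp(opt$par[3L]), 0.01, 64)
      th <- opt$par[4L]; ph <- opt$par[5L]
      mu <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      res <- opt$value
    }
    if (mu[3L] < 0 || (mu[3L] == 0 && mu[1L] < 0)) mu <- -mu  # canonical sign
    out$viso[v] <- viso; out$vic[v] <- vic; out$kappa[v] <- kappa
    out$mux[v] <- mu[1L]; out$muy[v] <- mu[2L]; out$muz[v] <- mu[3L]
    out$residual[v] <- sqrt(res)
    out$fitted[v] <- TRUE
    out$converged[v] <- !use_grid && opt$convergence == 0L
    if (verbose && ii %% 500L == 0L)
      message(sprintf("fit_noddi: %d / %d voxels", ii, n))
  }

  as_map <- function(x) image_grid(array(x, dim = shp), affine = dwi$affine)
  vf_ic <- (1 - out$viso) * out$vic
  vf_ec <- (1 - out$viso) * (1 - out$vic)
  structure(list(
    viso = as_map(out$viso), vic = as_map(out$vic), kappa = as_map(out$kappa),
    odi = as_map({
      o <- rep(NA_real_, nvox)
      ok <- !is.na(out$kappa)
      o[ok] <- odi_from_kappa(out$kappa[ok])
      o
    }),
    mu = image_grid(array(c(out$mux, out$muy, out$muz), dim = c(shp, 3L)),
                    affine = dwi$affine),
    vf_ic = as_map(vf_ic), vf_ec = as_map(vf_ec), vf_iso = as_map(out$viso),
    residual = as_map(out$residual),
    fitted = array(out$fitted, dim = shp),
    converged = array(out$converged, dim = shp)),
    class = "noddi_fit")
}

#' @export
print.noddi_fit <- function(x, ...) {
  n <- sum(x$fitted)
  cat(sprintf("<noddi_fit> %d fitted voxels (%d converged)\n",
              n, sum(x$converged)))
  if (n) cat(sprintf("  ODI range %.3f-%.3f, median VF_iso %.3f\n",
                     min(x$odi$data[x$fitted]), max(x$odi$data[x$fitted]),
                     stats::median(x$vf_iso$data[x$fitted])))
  invisible(x)
}
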