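# Diffusion tensor fit on the low-b shell (b < 1500 s/mm^2 strictly, so only
# the b = 0 and b = 1000 frames of the standard two-shell protocol enter).
# Weighted (signal^2-weighted) log-linear least squares: deterministic and
# exact on noise-free single-tensor data.

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`; the zero tensor
#' is assigned FA = 0.
#'
#' @param eigenvalues numeric vector of 3 non-negative eigenvalues
#' @return scalar in `[0, 1]`
#' @examples
#' fa(c(1.7e-3, 0.2e-3, 0.2e-3))  # 0.870
#' @export
fa <- function(eigenvalues) {
  l <- as.numeric(eigenvalues)
  stopifnot(length(l) == 3L)
  if (any(l < 0)) stop("domain error: negative eigenvalue", call. = FALSE)
  nrm <- sqrt(sum(l^2))
  if (nrm == 0) return(0)
  sqrt(1.5) * sqrt(sum((l - mean(l))^2)) / nrm
}

#' Mean diffusivity from tensor eigenvalues
#' @inheritParams fa
#' @return scalar, same units as the eigenvalues (mm^2/s)
#' @export
md <- function(eigenvalues) {
  l <- as.numeric(eigenvalues)
  stopifnot(length(l) == 3L)
  if (any(l < 0)) stop("domain error: negative eigenvalue", call. = FALSE)
  mean(l)
}

#' Fit the diffusion tensor voxelwise
#'
#' Only frames with `b < b_max` (plus the b = 0 frames) enter the fit. Voxels
#' where any diffusion-weighted frame exceeds the b = 0 signal are fitted on
#' log-clamped values (signal floor `1e-6 * S0`) and flagged. Negative
#' eigenvalues are clamped to 0 for the FA/MD maps, with the voxel flagged.
#'
#' @param dwi 4D [image_grid()]
#' @param scheme matching [gradient_scheme()]
#' @param mask binary mask of voxels to fit (default: all voxels)
#' @param b_max strict upper b-value bound for the sub-scheme (s/mm^2)
#' @return object of class `tensor_fit`: `tensor` (X x Y x Z x 6 lower-
#'   triangle components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `eigenvalues`
#'   (X x Y x Z x 3, descending), `e1` (principal eigenvector, X x Y x Z x 3),
#'   `fa`, `md` ([image_grid()]s), and logical `fitted` / `flagged` arrays
#' @export
fit_dti <- function(dwi, scheme, mask = NULL, b_max = 1500) {
  stopifnot(length(dim(dwi$data)) == 4L)
  b <- scheme$bvals
  if (dim(dwi$data)[4L] != length(b))
    stop("format error: frame count does not match scheme length", call. = FALSE)
  use <- b < b_max
  bs <- b[use]
  gs <- scheme$bvecs[use, , drop = FALSE]
  if (sum(bs > 0) < 6L)
    stop("scheme error: fewer than 6 diffusion-weighted directions below b_max",
         call. = FALSE)
  if (!any(bs == 0))
    stop("scheme error: no b = 0 frame below b_max", call. = FALSE)
  # rank check on the 6 tensor regressors
  Xd <- cbind(gs[, 1]^2, gs[, 2]^2, gs[, 3]^2,
              2 * gs[, 1] * gs[, 2], 2 * gs[, 1] * gs[, 3],
              2 * gs[, 2] * gs[, 3])[bs > 0, , drop = FALSE]
  if (qr(Xd)$rank < 6L)
    stop("scheme error: directions are collinear (rank-deficient design)",
         call. = FALSE)

  shp <- grid_shape(dwi)
  nvox <- prod(shp)
  m <- if (is.null(mask)) array(TRUE, dim = shp) else as_mask_array(mask)
  X <- cbind(1, -bs * gs[, 1]^2, -bs * gs[, 2]^2, -bs * gs[, 3]^2,
             -2 * bs * gs[, 1] * gs[, 2], -2 * bs * gs[, 1] * gs[, 3],
             -2 * bs * gs[, 2] * gs[, 3])
  dat <- matrix(dwi$data, nrow = nvox)[, use, drop = FALSE]

  tensor <- matrix(NA_real_, nvox, 6L)
  evals <- matrix(NA_real_, nvox, 3L)
  e1 <- matrix(NA_real_, nvox, 3L)
  fa_v <- md_v <- rep(NA_real_, nvox)
  fitted <- flagged <- rep(FALSE, nvox)

  vox <- which(m)
  for (v in vox) {
    S <- dat[v, ]
    s0 <- mean(S[bs == 0])
    if (!is.finite(s0) || s0 <= 0) { flagged[v] <- TRUE; next }
    flag <- any(S[bs > 0] >= s0) || any(S <= 0)
    Sc <- pmax(S, 1e-6 * s0)
    y <- log(Sc)
    w <- Sc^2
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% y), error = function(e) NULL)
    if (is.null(beta)) { flagged[v] <- TRUE; next }
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3L, 3L)
    ed <- eigen(D, symmetric = TRUE)
    lam <- ed$values            # descending
    if (any(lam < 0)) flag <- TRUE
    lamc <- pmax(lam, 0)
    tensor[v, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    evals[v, ] <- lam
    vec <- ed$vectors[, 1L]
    if (vec[3L] < 0) vec <- -vec
    e1[v, ] <- vec
    fa_v[v] <- fa(lamc)
    md_v[v] <- md(lamc)
    fitted[v] <- TRUE
    flagged[v] <- flag
  }

  as_map <- function(x) image_grid(array(x, dim = shp), affine = dwi$affine)
  structure(list(
    tensor = image_grid(array(tensor, dim = c(shp, 6L)), affine = dwi$affine),
    eigenvalues = image_grid(array(evals, dim = c(shp, 3L)), affine = dwi$affine),
    e1 = image_grid(array(e1, dim = c(shp, 3L)), affine = dwi$affine),
    fa = as_map(fa_v), md = as_map(md_v),
    fitted = array(fitted, dim = shp), flagged = array(flagged, dim = shp),
    b_max = b_max),
    class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("<tensor_fit> %d fitted voxels (%d flagged), b_max %g\n",
              sum(x$fitted), sum(x$flagged), x$b_max))
  invisible(x)
}
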