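#' Volumetric image on a regular grid
#'
#' Lightweight container for every volumetric map the package touches:
#' diffusion-weighted series, scalar maps (FA, MD, ODI, volume fractions),
#' orientation fields and binary masks. Data live in a 3D or 4D array; the
#' affine maps 0-based voxel indices to world coordinates in mm following the
#' NIfTI convention (voxel centre \code{(i,j,k)} sits at
#' \code{affine \%*\% c(i,j,k,1)}).
#'
#' @param data 3D or 4D numeric (or logical) array. For 4D data the last axis
#'   indexes diffusion volumes (or vector components).
#' @param affine 4x4 invertible voxel-to-world transform. Defaults to a scaled
#'   identity built from `voxel_size`.
#' @param voxel_size length-3 positive voxel edge lengths in mm. Derived from
#'   `affine` column norms when omitted.
#' @return An object of class `image_grid` with fields `data`, `affine`,
#'   `voxel_size`.
#' @examples
#' g <- image_grid(array(0, c(4, 4, 4)), voxel_size = c(2.5, 2.5, 2.5))
#' voxel_volume(g)
#' @export
image_grid <- function(data, affine = NULL, voxel_size = NULL) {
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array", call. = FALSE)
  if (is.null(affine)) {
    if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  if (is.null(voxel_size))
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(list(data = data, affine = unname(affine), voxel_size = voxel_size),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_grid> %s voxels, voxel size %s mm\n",
              paste(d, collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$data)

#' Volume of one voxel in mm^3
#' @param grid an `image_grid`
#' @return scalar mm^3
#' @export
voxel_volume <- function(grid) abs(det(as.matrix(grid$affine)[1:3, 1:3]))

grid_shape <- function(grid) dim(grid$data)[1:3]

#' Convert between world (mm) and 0-based voxel coordinates
#'
#' @param grid an `image_grid`
#' @param points n x 3 matrix of coordinates
#' @return n x 3 matrix
#' @export
world_to_voxel <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  inv <- solve(grid$affine)
  t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  t(grid$affine[1:3, 1:3] %*% t(points) + grid$affine[1:3, 4])
}

#' Do two grids share the same geometry?
#'
#' Shape must match exactly; affines within `tol` elementwise.
#' @param a,b `image_grid` objects
#' @param tol elementwise affine tolerance
#' @return logical
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  all(grid_shape(a) == grid_shape(b)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "mask") {
  if (!same_grid(a, b))
    stop(sprintf("geometry error: %s grid does not match reference (shape/affine)", what),
         call. = FALSE)
  invisible(TRUE)
}

# Coerce a mask-like input (image_grid or array) to a logical 3D array.
as_mask_array <- function(mask, reference = NULL) {
  if (inherits(mask, "image_grid")) {
    if (!is.null(reference)) stop_if_grid_mismatch(mask, reference)
    mask <- mask$data
  }
  v <- as.numeric(mask)
  near0 <- abs(v) <= 1e-6
  near1 <- abs(v - 1) <= 1e-6
  if (!all(near0 | near1))
    stop("validation error: mask contains values other than 0/1", call. = FALSE)
  array(near1, dim = dim(mask)[1:3])
}

#' Diffusion gradient scheme
#'
#' b-values (s/mm^2) and unit gradient directions defining a multi-shell
#' acquisition. Directions at b > 0 are renormalized to unit length; a zero
#' vector at b > 0 is rejected.
#'
#' @param bvals numeric vector of b-values, at least one equal to 0
#' @param bvecs n x 3 matrix of gradient directions
#' @return object of class `gradient_scheme` with fields `bvals` (vector) and
#'   `bvecs` (n x 3 matrix, unit rows where b > 0)
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  if (length(bvals) != nrow(bvecs))
    stop("format error: number of b-values and gradient directions differ", call. = FALSE)
  if (any(bvals < 0)) stop("validation error: negative b-value", call. = FALSE)
  if (!any(bvals == 0)) stop("validation error: scheme has no b = 0 entry", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  dwi <- bvals > 0
  if (any(dwi & nrm < 1e-8))
    stop("validation error: zero gradient vector at b > 0", call. = FALSE)
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  tb <- table(x$bvals)
  cat("<gradient_scheme>", length(x$bvals), "volumes:",
      paste(sprintf("%s x b=%s", tb, names(tb)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gradient_scheme <- function(x) length(x$bvals)

#' Streamline tractogram
#'
#' Ordered 3D point sequences in world mm with tracking metadata. Consecutive
#' points are spaced exactly `step_size_mm` apart (relative tolerance 1e-6).
#'
#' @param streamlines list of n_i x 3 numeric matrices (n_i >= 2)
#' @param step_size_mm fixed tracking step in mm
#' @param provenance free-form metadata list (tracker settings, seeds, flags)
#' @param check validate point spacing (disable for huge tractograms)
#' @return object of class `tractogram`
#' @export
tractogram <- function(streamlines, step_size_mm, provenance = list(), check = TRUE) {
  stopifnot(is.list(streamlines), step_size_mm > 0)
  streamlines <- lapply(streamlines, function(s) {
    s <- matrix(as.numeric(s), ncol = 3L)
    if (nrow(s) < 2L)
      stop("validation error: streamline with fewer than 2 points", call. = FALSE)
    s
  })
  if (check && length(streamlines)) {
    for (s in streamlines) {
      d <- sqrt(rowSums(diff(s)^2))
      if (max(abs(d - step_size_mm)) > 1e-6 * step_size_mm)
        stop("validation error: point spacing differs from step size", call. = FALSE)
    }
  }
  structure(list(streamlines = streamlines, step_size_mm = step_size_mm,
                 provenance = provenance),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  npts <- if (n) vapply(x$streamlines, nrow, 1L) else integer()
  cat(sprintf("<tractogram> %d streamlines, step %.3g mm", n, x$step_size_mm))
  if (n) cat(sprintf(", lengths %.1f-%.1f mm",
                     (min(npts) - 1) * x$step_size_mm, (max(npts) - 1) * x$step_size_mm))
  cat("\n")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Streamline lengths in mm
#' @param t a `tractogram`
#' @return numeric vector
#' @export
streamline_lengths <- function(t) {
  vapply(t$streamlines, function(s) (nrow(s) - 1) * t$step_size_mm, numeric(1))
}
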