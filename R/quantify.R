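# Edema-condition quantification: which edema voxels are traversed by both
# trackers (DN), by the tensor-derived streamlines only (D-only), or by the
# dispersion-terminated streamlines only (N-only), with the derived volume,
# PIV, lesion-to-tract distance and distance-weighted indices.

#' Classify edema voxels by tracker agreement
#'
#' @param dti_mask,noddi_mask,edema_mask binary [image_grid()]s on one grid
#' @return object of class `condition_masks` with binary [image_grid()]s
#'   `dn` (both), `d_only`, `n_only`; the three are pairwise disjoint and
#'   their union is `(dti | noddi) & edema`
#' @export
condition_masks <- function(dti_mask, noddi_mask, edema_mask) {
  stop_if_grid_mismatch(noddi_mask, dti_mask, "noddi mask")
  stop_if_grid_mismatch(edema_mask, dti_mask, "edema mask")
  d <- as_mask_array(dti_mask$data)
  n <- as_mask_array(noddi_mask$data)
  e <- as_mask_array(edema_mask$data)
  g <- function(m) image_grid(array(as.numeric(m), dim = dim(m)),
                              affine = dti_mask$affine)
  structure(list(dn = g(d & n & e), d_only = g(d & !n & e),
                 n_only = g(!d & n & e)), class = "condition_masks")
}

#' Percentage of involved volume
#'
#' Ratio of a condition volume to the whole-tract volume (the union of the
#' tensor- and dispersion-derived tract masks).
#'
#' @param condition_volume,cst_volume volumes in mm^3;
#'   `condition_volume <= cst_volume`, `cst_volume > 0`
#' @return ratio in `[0, 1]`
#' @export
piv <- function(condition_volume, cst_volume) {
  if (cst_volume <= 0)
    stop("undefined-metric error: zero tract volume", call. = FALSE)
  if (condition_volume > cst_volume + 1e-9)
    stop("validation error: condition volume exceeds tract volume", call. = FALSE)
  if (condition_volume < 0)
    stop("validation error: negative volume", call. = FALSE)
  condition_volume / cst_volume
}

#' Lesion-to-tract distance
#'
#' Minimum Euclidean world-mm distance from the lesion boundary (lesion voxels
#' with at least one non-lesion 6-neighbour, grid edges counting as outside)
#' to any tract voxel, measured between voxel centres. Overlapping masks give
#' 0.
#'
#' @param lesion_mask,cst_mask non-empty binary [image_grid()]s on one grid
#' @return distance in mm
#' @export
ltd <- function(lesion_mask, cst_mask) {
  stop_if_grid_mismatch(cst_mask, lesion_mask, "tract mask")
  les <- as_mask_array(lesion_mask$data)
  cst <- as_mask_array(cst_mask$data)
  if (!any(les) || !any(cst))
    stop("parameter error: empty mask", call. = FALSE)
  if (any(les & cst)) return(0)
  bnd <- les & !erode6(les)
  pb <- voxel_to_world(lesion_mask, which(bnd, arr.ind = TRUE) - 1L)
  pc <- voxel_to_world(lesion_mask, which(cst, arr.ind = TRUE) - 1L)
  min_pair_dist(pb, pc)
}

# 6-connected erosion; neighbours beyond the grid edge count as background
erode6 <- function(m) {
  d <- dim(m)
  out <- m > 0
  pad_shift <- function(a, ax, by) {
    res <- array(FALSE, dim = d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (by > 0) { idx_dst[[ax]] <- seq_len(d[ax] - by)
                  idx_src[[ax]] <- seq_len(d[ax] - by) + by }
    else        { idx_dst[[ax]] <- seq_len(d[ax] + by) - by
                  idx_src[[ax]] <- seq_len(d[ax] + by) }
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    res
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & pad_shift(m > 0, ax, by)
  out
}

# chunked exact minimum pairwise distance between two point sets (mm)
min_pair_dist <- function(a, b, chunk = 2048L) {
  best <- Inf
  for (s in seq(1L, nrow(a), by = chunk)) {
    ai <- a[s:min(nrow(a), s + chunk - 1L), , drop = FALSE]
    d2 <- outer(rowSums(ai^2), rowSums(b^2), `+`) - 2 * ai %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Distance-weighted involvement indices
#'
#' Divides a condition volume and PIV by the lesion-to-tract distance. A zero
#' distance (tract touching the lesion) leaves the indices undefined and
#' flagged rather than infinite.
#'
#' @param volume condition volume, mm^3
#' @param piv_value condition PIV
#' @param ltd_mm lesion-to-tract distance, mm
#' @return list with `volume_ltd`, `piv_ltd`, and logical `undefined`
#' @export
weighted_indices <- function(volume, piv_value, ltd_mm) {
  if (ltd_mm < 0) stop("validation error: negative distance", call. = FALSE)
  if (ltd_mm == 0)
    return(list(volume_ltd = NA_real_, piv_ltd = NA_real_, undefined = TRUE))
  list(volume_ltd = volume / ltd_mm, piv_ltd = piv_value / ltd_mm,
       undefined = FALSE)
}

#' Mean volume fractions over a region
#'
#' Arithmetic voxel means of the absolute NODDI fractions inside a mask; the
#' three means sum to 1 by linearity of the per-voxel identity.
#'
#' @param fit a `noddi_fit` from [fit_noddi()]
#' @param mask non-empty binary mask over fitted voxels
#' @return named vector `c(vf_ic, vf_ec, vf_iso)`
#' @export
fraction_summary <- function(fit, mask) {
  m <- as_mask_array(mask)
  sel <- m & fit$fitted
  if (!any(sel))
    stop("parameter error: empty mask (no fitted voxels)", call. = FALSE)
  c(vf_ic = mean(fit$vf_ic$data[sel]),
    vf_ec = mean(fit$vf_ec$data[sel]),
    vf_iso = mean(fit$vf_iso$data[sel]))
}

#' Per-subject edema-tract metrics table
#'
#' Convenience wrapper assembling the full quantification row: per-condition
#' volumes, PIVs, lesion-to-tract distance, distance-weighted indices and
#' (when a fit is supplied) mean fractions in the DN and N-only conditions.
#'
#' @param dti_mask,noddi_mask,edema_mask,lesion_mask binary [image_grid()]s
#' @param fit optional `noddi_fit` for fraction summaries
#' @return one-row `data.frame`
#' @export
quantify_tracts <- function(dti_mask, noddi_mask, edema_mask, lesion_mask,
                            fit = NULL) {
  cm <- condition_masks(dti_mask, noddi_mask, edema_mask)
  vv <- voxel_volume(dti_mask)
  union_mask <- image_grid(
    array(as.numeric(as_mask_array(dti_mask$data) | as_mask_array(noddi_mask$data)),
          dim = grid_shape(dti_mask)), affine = dti_mask$affine)
  cst_vol <- mask_volume(union_mask)
  vols <- vapply(cm, mask_volume, numeric(1))
  pivs <- vapply(vols, piv, numeric(1), cst_volume = cst_vol)
  ltd_mm <- ltd(lesion_mask, union_mask)
  out <- data.frame(
    cst_volume_mm3 = cst_vol,
    dn_volume_mm3 = vols[["dn"]], d_only_volume_mm3 = vols[["d_only"]],
    n_only_volume_mm3 = vols[["n_only"]],
    dn_piv = pivs[["dn"]], d_only_piv = pivs[["d_only"]],
    n_only_piv = pivs[["n_only"]],
    ltd_mm = ltd_mm)
  for (cond in c("dn", "d_only", "n_only")) {
    w <- weighted_indices(vols[[cond]], pivs[[cond]], ltd_mm)
    out[[paste0(cond, "_volume_ltd")]] <- w$volume_ltd
    out[[paste0(cond, "_piv_ltd")]] <- w$piv_ltd
  }
  if (!is.null(fit)) {
    for (cond in c("dn", "n_only")) {
      sel <- as_mask_array(cm[[cond]]$data) & fit$fitted
      if (any(sel)) {
        fs <- fraction_summary(fit, cm[[cond]])
        out[[paste0(cond, "_vf_ic")]] <- fs[["vf_ic"]]
        out[[paste0(cond, "_vf_ec")]] <- fs[["vf_ec"]]
        out[[paste0(cond, "_vf_iso")]] <- fs[["vf_iso"]]
      } else {
        out[[paste0(cond, "_vf_ic")]] <- NA_real_
        out[[paste0(cond, "_vf_ec")]] <- NA_real_
        out[[paste0(cond, "_vf_iso")]] <- NA_real_
      }
    }
  }
  out
}
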