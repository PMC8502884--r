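#' Streamline stopping rule
#'
#' Couples a scalar metric map with a termination mode: `"floor"` terminates
#' propagation where the metric drops to or below the threshold (the standard
#' FA rule, FA <= 0.20) and `"ceiling"` where it rises to or above it (the
#' dispersion rule: coherent white matter has low ODI, gray matter high ODI,
#' so tracking continues while ODI < threshold).
#'
#' @param metric_map scalar [image_grid()] (FA or ODI); `NA` voxels are
#'   treated as terminal
#' @param mode `"floor"` or `"ceiling"`
#' @param threshold scalar within the metric's range
#' @param max_angle_deg maximum turning angle between consecutive steps
#'   (termination at or above it), in (0, 90]
#' @param step_mm Euler step length
#' @param length_bounds_mm accepted streamline length range `[min, max]`
#' @return object of class `stop_rule`
#' @export
stop_rule <- function(metric_map, mode = c("floor", "ceiling"), threshold,
                      max_angle_deg = 60, step_mm = 0.5,
                      length_bounds_mm = c(30, 300)) {
  mode <- match.arg(mode)
  stopifnot(inherits(metric_map, "image_grid"),
            is.numeric(threshold), length(threshold) == 1L,
            max_angle_deg > 0, max_angle_deg <= 90, step_mm > 0,
            length(length_bounds_mm) == 2L,
            length_bounds_mm[1] < length_bounds_mm[2])
  rng <- range(metric_map$data, na.rm = TRUE)
  if (threshold < rng[1] - 1 || threshold > rng[2] + 1)
    warning("threshold lies far outside the metric's observed range")
  structure(list(metric_map = metric_map, mode = mode, threshold = threshold,
                 max_angle_deg = max_angle_deg, step_mm = step_mm,
                 length_bounds_mm = length_bounds_mm), class = "stop_rule")
}

#' Inclusion/exclusion ROI set
#'
#' @param include list of binary inclusion masks ([image_grid()]); a kept
#'   streamline must intersect every one (for the corticospinal tract: a
#'   sensorimotor slab and a brainstem slab)
#' @param exclude list of binary exclusion masks; touching any removes the
#'   streamline (e.g. cerebellum, cross-hemisphere)
#' @return object of class `roi_set`
#' @export
roi_set <- function(include, exclude = list()) {
  if (!is.list(include)) include <- list(include)
  if (!is.list(exclude)) exclude <- list(exclude)
  if (length(include) == 0L)
    stop("parameter error: at least one inclusion ROI required", call. = FALSE)
  structure(list(include = include, exclude = exclude), class = "roi_set")
}

# Does a streamline (world-mm points) enter any voxel of `mask`?
streamline_hits <- function(points, mask_grid) {
  v <- round(world_to_voxel(mask_grid, points))
  shp <- grid_shape(mask_grid)
  ok <- v[, 1] >= 0 & v[, 1] < shp[1] & v[, 2] >= 0 & v[, 2] < shp[2] &
    v[, 3] >= 0 & v[, 3] < shp[3]
  if (!any(ok)) return(FALSE)
  v <- v[ok, , drop = FALSE]
  lin <- 1L + v[, 1] + shp[1] * (v[, 2] + shp[2] * v[, 3])
  any(mask_grid$data[lin] != 0)
}

passes_rois <- function(points, rois) {
  for (ex in rois$exclude) if (streamline_hits(points, ex)) return(FALSE)
  for (inc in rois$include) if (!streamline_hits(points, inc)) return(FALSE)
  TRUE
}

#' Deterministic streamline tractography
#'
#' Seeds are drawn uniformly at random inside the seed-mask voxels; each seed
#' is propagated bidirectionally by fixed-step Euler integration with
#' nearest-neighbour direction lookup and trilinear stopping-metric
#' interpolation, the local direction sign-aligned with the incoming one.
#' Propagation terminates on the stopping rule, a turning angle at or above
#' the maximum, an invalid voxel, or leaving the grid. Streamlines outside the
#' length bounds are discarded; when `rois` is given, streamlines failing the
#' ROI filter are discarded too, so the quota counts finally reconstructed
#' streamlines. Seeding repeats until `target_count` streamlines are accepted
#' or `max_attempts` seeds have been spent, in which case the partial
#' tractogram carries `provenance$starved = TRUE`.
#'
#' @param direction_field X x Y x Z x 3 [image_grid()] of unit directions
#'   (DTI principal eigenvector or NODDI orientation)
#' @param stop a [stop_rule()]
#' @param seed_mask binary [image_grid()] of seed voxels
#' @param target_count streamlines to accept
#' @param rng_seed integer seed for the seed-position RNG
#' @param rois optional [roi_set()] applied inside the acceptance loop
#' @param valid_mask optional binary mask of voxels where the direction field
#'   is trustworthy (e.g. NODDI fit success and VF_iso < 0.95); others are
#'   terminal
#' @param max_attempts seed budget before giving up (default 100 x quota)
#' @param batch_size seeds per compiled-core call
#' @return a [tractogram()]; `provenance` records mode, threshold, seed,
#'   attempts, and the starvation flag
#' @export
track <- function(direction_field, stop, seed_mask, target_count = 3000L,
                  rng_seed = 1L, rois = NULL, valid_mask = NULL,
                  max_attempts = 100L * target_count,
                  batch_size = 20000L) {
  stopifnot(inherits(direction_field, "image_grid"),
            inherits(stop, "stop_rule"))
  shp <- grid_shape(direction_field)
  stop_if_grid_mismatch(stop$metric_map, direction_field, "metric map")
  seed_arr <- as_mask_array(seed_mask, direction_field)
  seed_vox <- which(seed_arr, arr.ind = TRUE) - 1L  # 0-based
  if (nrow(seed_vox) == 0L)  # base::stop: the `stop` argument shadows it here
    base::stop("parameter error: empty seed mask", call. = FALSE)
  valid <- if (is.null(valid_mask)) array(1L, dim = shp) else
    array(as.integer(as_mask_array(valid_mask, direction_field)), dim = shp)
  inv <- solve(direction_field$affine)
  rng <- local_rng(rng_seed)

  accepted <- vector("list", target_count)
  n_acc <- 0L
  attempts <- 0L
  while (n_acc < target_count && attempts < max_attempts) {
    nb <- min(batch_size, max_attempts - attempts)
    rows <- floor(rng$unif(nb) * nrow(seed_vox)) + 1L
    offs <- matrix(rng$unif(3L * nb) - 0.5, nb, 3L)
    seeds_vox <- seed_vox[rows, , drop = FALSE] + offs
    seeds_world <- voxel_to_world(direction_field, seeds_vox)
    res <- .track_batch(direction_field$data, stop$metric_map$data, valid,
                        as.integer(shp), seeds_world, inv,
                        stop$step_mm, stop$max_angle_deg, stop$threshold,
                        stop$mode == "ceiling",
                        stop$length_bounds_mm[1], stop$length_bounds_mm[2])
    attempts <- attempts + nb
    for (sl in res) {
      if (!is.null(rois) && !passes_rois(sl, rois)) next
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- sl
      if (n_acc >= target_count) break
    }
  }
  tractogram(accepted[seq_len(n_acc)], step_size_mm = stop$step_mm,
             provenance = list(mode = stop$mode, threshold = stop$threshold,
                               max_angle_deg = stop$max_angle_deg,
                               rng_seed = rng_seed, attempts = attempts,
                               target_count = target_count,
                               starved = n_acc < target_count),
             check = FALSE)
}

#' Filter streamlines by inclusion/exclusion ROIs
#'
#' Keeps streamlines that intersect every inclusion mask and no exclusion
#' mask; intersection means any point falls inside a mask voxel.
#'
#' @param t a [tractogram()]
#' @param rois a [roi_set()]
#' @return filtered [tractogram()]
#' @export
filter_by_rois <- function(t, rois) {
  stopifnot(inherits(t, "tractogram"), inherits(rois, "roi_set"))
  keep <- vapply(t$streamlines, passes_rois, logical(1), rois = rois)
  tractogram(t$streamlines[keep], step_size_mm = t$step_size_mm,
             provenance = c(t$provenance, list(roi_filtered = TRUE)),
             check = FALSE)
}

#' Voxelize a tractogram into a binary visitation mask
#'
#' A voxel is set where at least one streamline point maps into it; the tract
#' volume is the voxel count times the voxel volume.
#'
#' @param t a [tractogram()]
#' @param grid [image_grid()] defining the target geometry
#' @return binary [image_grid()]
#' @export
tract_mask <- function(t, grid) {
  shp <- grid_shape(grid)
  out <- array(0, dim = shp)
  for (s in t$streamlines) {
    v <- round(world_to_voxel(grid, s))
    ok <- v[, 1] >= 0 & v[, 1] < shp[1] & v[, 2] >= 0 & v[, 2] < shp[2] &
      v[, 3] >= 0 & v[, 3] < shp[3]
    if (!any(ok)) next
    v <- v[ok, , drop = FALSE]
    lin <- 1L + v[, 1] + shp[1] * (v[, 2] + shp[2] * v[, 3])
    out[lin] <- 1
  }
  image_grid(out, affine = grid$affine)
}

#' Volume of a binary mask in mm^3
#' @param mask binary [image_grid()]
#' @return scalar mm^3
#' @export
mask_volume <- function(mask) {
  sum(as_mask_array(mask$data)) * voxel_volume(mask)
}

#' Do streamlines traverse a region?
#'
#' Fraction of streamlines with at least one point inside the mask.
#'
#' @param t a [tractogram()]
#' @param mask binary [image_grid()]
#' @return fraction in `[0, 1]`
#' @export
traversal_fraction <- function(t, mask) {
  if (length(t$streamlines) == 0L) return(0)
  mean(vapply(t$streamlines, streamline_hits, logical(1), mask_grid = mask))
}
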