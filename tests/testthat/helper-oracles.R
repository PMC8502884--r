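# Independent oracles used by the test suite. Each re-derives a quantity by a
# different route (brute force, enumeration, dense quadrature) than the
# implementation under test.

# Trapezoidal integral of the empirical ROC curve.
oracle_auc_trapezoid <- function(values, labels, larger) {
  pos <- values[labels == larger]
  neg <- values[labels != larger]
  ts <- sort(unique(values), decreasing = TRUE)
  tpr <- c(0, vapply(ts, function(t) mean(pos >= t), numeric(1)))
  fpr <- c(0, vapply(ts, function(t) mean(neg >= t), numeric(1)))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Exhaustive Youden scan over all midpoint thresholds (plus infinities).
oracle_youden_scan <- function(values, labels, larger) {
  pos <- values[labels == larger]
  neg <- values[labels != larger]
  sv <- sort(unique(values))
  ths <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  j <- vapply(ths, function(t) mean(pos > t) + mean(neg <= t) - 1, numeric(1))
  max(j)
}

# All-pairs lesion-boundary to tract distance on small grids.
oracle_ltd_bruteforce <- function(lesion, cst, voxel_size) {
  les <- which(lesion > 0, arr.ind = TRUE)
  cstv <- which(cst > 0, arr.ind = TRUE)
  d <- dim(lesion)
  is_boundary <- function(p) {
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      q <- p
      q[ax] <- q[ax] + s
      if (any(q < 1L) || any(q > d)) return(TRUE)
      if (lesion[q[1], q[2], q[3]] == 0) return(TRUE)
    }
    FALSE
  }
  bnd <- les[apply(les, 1L, is_boundary), , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(bnd))) for (j in seq_len(nrow(cstv)))
    best <- min(best, sum(((bnd[i, ] - cstv[j, ]) * voxel_size)^2))
  sqrt(best)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_wilcoxon_enum <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wpos_all <- as.numeric(signs %*% r)
  tot <- sum(r)
  w_obs <- sum(r[d > 0])
  w_min <- min(w_obs, tot - w_obs)
  min(1, mean(wpos_all <= w_min) + mean(wpos_all >= tot - w_min))
}

# Random symmetric positive-definite diffusion tensor (mm^2/s scale).
random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3L)
  crossprod(A) * 2e-4 + diag(3) * 1e-4
}

# Random 3D rotation matrix.
random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3L)))
}

# Binary image_grid from an array.
as_grid <- function(arr, voxel = 1) {
  image_grid(array(as.numeric(arr), dim = dim(arr)),
             voxel_size = rep(voxel, 3))
}
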