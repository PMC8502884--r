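#' Write an image grid to NIfTI-1
#'
#' @param grid an [image_grid()]
#' @param path output `.nii` or `.nii.gz` path
#' @return `path`, invisibly
#' @export
write_nifti_grid <- function(grid, path) {
  img <- RNifti::asNifti(array(as.numeric(grid$data), dim = dim(grid$data)))
  # pixdim (one entry per data dimension) must be set before the forms or the
  # scale part is dropped on write
  nd <- length(dim(grid$data))
  img <- RNifti::`pixdim<-`(img, c(grid$voxel_size, rep(1, nd - 3L)))
  aff <- structure(grid$affine, code = 2L)
  img <- RNifti::`qform<-`(img, aff)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into an image grid
#'
#' @param path `.nii`/`.nii.gz` file
#' @return an [image_grid()]
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  image_grid(array(as.numeric(img), dim = dim(img)), affine = aff)
}

#' Read FSL-dialect bval/bvec text files
#'
#' FSL dialect: one whitespace-delimited row of b-values; three rows of
#' direction components (x, y, z).
#'
#' @param bval_path,bvec_path text files
#' @return a [gradient_scheme()]
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L)
    stop("format error: bvec file must have exactly 3 rows", call. = FALSE)
  comp <- lapply(rows, function(r) scan(text = r, what = numeric(), quiet = TRUE))
  n <- unique(lengths(comp))
  if (length(n) != 1L)
    stop("format error: bvec rows have unequal lengths", call. = FALSE)
  if (n != length(bvals))
    stop("format error: bval/bvec entry counts differ", call. = FALSE)
  gradient_scheme(bvals, cbind(comp[[1]], comp[[2]], comp[[3]]))
}

#' Write FSL-dialect bval/bvec text files
#' @param scheme a [gradient_scheme()]
#' @param bval_path,bvec_path output paths
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Read a 4D diffusion-weighted series with its gradient scheme
#'
#' @param volume_path 4D NIfTI file
#' @param bval_path,bvec_path FSL-dialect gradient text files
#' @return list with elements `dwi` ([image_grid()]) and `scheme`
#'   ([gradient_scheme()])
#' @export
read_dwi <- function(volume_path, bval_path, bvec_path) {
  grid <- read_nifti_grid(volume_path)
  if (length(dim(grid$data)) != 4L)
    stop("format error: DWI volume must be 4D", call. = FALSE)
  scheme <- read_bvals_bvecs(bval_path, bvec_path)
  if (dim(grid$data)[4L] != length(scheme$bvals))
    stop(sprintf("format error: %d DWI frames but %d gradient entries",
                 dim(grid$data)[4L], length(scheme$bvals)), call. = FALSE)
  list(dwi = grid, scheme = scheme)
}

#' Write a DWI series plus gradient files
#' @param dwi 4D [image_grid()]
#' @param scheme matching [gradient_scheme()]
#' @param volume_path,bval_path,bvec_path output paths
#' @export
write_dwi <- function(dwi, scheme, volume_path, bval_path, bvec_path) {
  if (dim(dwi$data)[4L] != length(scheme$bvals))
    stop("format error: frame count does not match scheme length", call. = FALSE)
  write_nifti_grid(dwi, volume_path)
  write_bvals_bvecs(scheme, bval_path, bvec_path)
  invisible(volume_path)
}

#' Read a binary mask aligned to a reference grid
#'
#' The mask must match the reference shape and affine (tolerance 1e-4).
#' Values within 1e-6 of 0/1 are snapped; anything else is rejected, guarding
#' against interpolated masks.
#'
#' @param path NIfTI mask file
#' @param reference [image_grid()] defining the expected geometry
#' @return binary [image_grid()] (data strictly 0/1)
#' @export
read_mask <- function(path, reference) {
  g <- read_nifti_grid(path)
  ref3 <- reference
  stop_if_grid_mismatch(g, ref3)
  m <- as_mask_array(g$data)
  image_grid(array(as.numeric(m), dim = dim(m)), affine = g$affine)
}

#' Write a binary mask
#' @param mask binary [image_grid()]
#' @param path output NIfTI path
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_array(mask$data)
  write_nifti_grid(image_grid(array(as.integer(m), dim = dim(m)),
                              affine = mask$affine), path)
}

# ---- TCK tractogram format (MRtrix) -----------------------------------------
# Text header terminated by "END", then little-endian float32 triplets in
# world mm; streamlines separated by a NaN triplet, stream terminated by an
# Inf triplet. TCK is affine-unambiguous (always world mm), which is why it is
# the package's tractogram standard.

#' Write a tractogram in TCK format
#'
#' @param t a [tractogram()]
#' @param path output `.tck` path
#' @return `path`, invisibly
#' @export
write_tractogram <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  prov <- t$provenance
  prov_lines <- if (length(prov))
    vapply(names(prov), function(k)
      sprintf("%s: %s", k, paste(format(prov[[k]]), collapse = " ")), character(1))
  else character()
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(t$streamlines)),
              sprintf("step_size: %.6g", t$step_size_mm),
              prov_lines)
  # two-pass offset: header length depends on the printed offset itself
  offset <- 0L
  for (i in 1:3) {
    lines <- c(header, sprintf("file: . %d", offset), "END")
    n <- sum(nchar(lines, type = "bytes")) + length(lines)  # newline per line
    if (n == offset) break
    offset <- n
  }
  writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' @param path `.tck` file
#' @param step_size_mm override the step size recorded in the header
#' @return a [tractogram()]
#' @export
read_tractogram <- function(path, step_size_mm = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 14L || rawToChar(raw[1:13]) != "mrtrix tracks")
    stop("format error: not a TCK file (bad magic)", call. = FALSE)
  # locate END line in the raw bytes (the payload after it is binary)
  m <- grepRaw("\nEND\n", raw, fixed = TRUE)
  if (length(m) == 0L) stop("format error: TCK header without END", call. = FALSE)
  header <- strsplit(rawToChar(raw[seq_len(m[1] - 1L)]), "\n", fixed = TRUE)[[1]][-1]
  kv <- strsplit(header, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  dt <- vals[match("datatype", keys)]
  if (is.na(dt) || dt != "Float32LE")
    stop("format error: unsupported TCK datatype", call. = FALSE)
  fileline <- vals[match("file", keys)]
  offset <- as.integer(sub("^\\. ", "", fileline))
  if (is.na(offset)) stop("format error: TCK header missing file offset", call. = FALSE)
  nfloat <- (length(raw) - offset) %/% 4L
  v <- readBin(raw[(offset + 1L):length(raw)], "numeric", n = nfloat,
               size = 4L, endian = "little")
  if (length(v) %% 3L != 0L) stop("format error: truncated TCK point data", call. = FALSE)
  pts <- matrix(v, ncol = 3L, byrow = TRUE)
  inf_rows <- which(is.infinite(pts[, 1]))
  if (length(inf_rows) == 0L)
    stop("format error: TCK stream missing terminator", call. = FALSE)
  pts <- pts[seq_len(inf_rows[1] - 1L), , drop = FALSE]
  nan_rows <- which(is.nan(pts[, 1]))
  starts <- c(1L, nan_rows + 1L)
  ends <- c(nan_rows - 1L, nrow(pts))
  keep <- starts <= ends
  streamlines <- Map(function(s, e) pts[s:e, , drop = FALSE],
                     starts[keep], ends[keep])
  if (is.null(step_size_mm)) {
    step_size_mm <- suppressWarnings(as.numeric(vals[match("step_size", keys)]))
    if (is.na(step_size_mm)) {
      step_size_mm <- if (length(streamlines))
        sqrt(sum((streamlines[[1]][2, ] - streamlines[[1]][1, ])^2)) else 1
    }
  }
  prov <- as.list(vals[!keys %in% c("datatype", "count", "step_size", "file")])
  names(prov) <- keys[!keys %in% c("datatype", "count", "step_size", "file")]
  tractogram(streamlines, step_size_mm = step_size_mm, provenance = prov,
             check = FALSE)
}
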