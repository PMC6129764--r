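# NIfTI input/output and the 4D volume <-> masked time-series matrix bridge.
#
# Voxel linear order throughout the package: column-major over (X fastest,
# then Y, then Z) -- R's native array order. Every module that maps between
# voxels and matrix columns relies on this single convention.

#' Construct a 4D volume
#'
#' The in-memory unit of image data: a real X x Y x Z x T array, a 4x4
#' voxel-to-world affine (mm), and the repetition time in seconds. 3D images
#' are carried as T = 1.
#'
#' @param data Numeric array, 3D or 4D.
#' @param affine 4x4 voxel-to-world transform (voxel-center convention,
#'   0-based voxel indices).
#' @param tr Repetition time in seconds.
#' @param descrip Free-text description.
#' @return A `volume4d` object.
#' @export
volume4d <- function(data, affine = diag(4), tr = 1, descrip = "") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("'data' must be a 3D or 4D array")
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  affine <- matrix(as.numeric(affine), 4L, 4L)  # drop foreign attributes
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("'tr' must be a single positive number")
  structure(list(data = data, affine = unname(affine), tr = as.numeric(tr),
                 descrip = as.character(descrip)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d, %d frame(s), TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Construct a brain mask
#'
#' @param data Logical or 0/1 numeric 3D array.
#' @param affine 4x4 voxel-to-world transform.
#' @return A `brain_mask` object.
#' @export
brain_mask <- function(data, affine = diag(4)) {
  if (is.numeric(data)) data <- data != 0
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("mask 'data' must be a logical 3D array")
  if (!any(data)) stop("mask has no voxels set")
  structure(list(data = data, affine = unname(as.matrix(affine))),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s, %d voxels\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

# Shapes exact, affines within 1e-4 mm per element.
check_grid <- function(a_dim, a_affine, b_dim, b_affine, what = "inputs") {
  if (!all(a_dim[1:3] == b_dim[1:3]))
    stop(sprintf("grid mismatch between %s: shapes %s vs %s", what,
                 paste(a_dim[1:3], collapse = "x"),
                 paste(b_dim[1:3], collapse = "x")))
  if (max(abs(a_affine - b_affine)) > 1e-4)
    stop(sprintf("grid mismatch between %s: affines differ by more than 1e-4",
                 what))
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii` or `.nii.gz` transparently; a 3D file yields a volume with
#' T = 1. The repetition time is taken from the header time step; a `tr`
#' argument overrides it (with a warning when the two disagree).
#'
#' @param path Path to a NIfTI-1 file, plain or gzipped.
#' @param tr Optional repetition-time override in seconds.
#' @return A [volume4d()] object.
#' @export
read_volume <- function(path, tr = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("unsupported image dimensionality in '", path, "'")
  pd <- RNifti::pixdim(img)
  header_tr <- if (length(pd) >= 4L && is.finite(pd[4]) && pd[4] > 0)
    unname(pd[4]) else 1
  if (!is.null(tr)) {
    if (abs(tr - header_tr) > 1e-6)
      warning(sprintf("TR override %g s differs from header time step %g s",
                      tr, header_tr))
    header_tr <- tr
  }
  volume4d(data, affine = unclass(RNifti::xform(img)), tr = header_tr)
}

#' Read a 3D NIfTI file as a brain mask
#'
#' Nonzero voxels become mask members.
#'
#' @param path Path to a 3D NIfTI file.
#' @return A [brain_mask()] object.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  brain_mask(vol$data[, , , 1] != 0, affine = vol$affine)
}

#' Write a volume as NIfTI-1
#'
#' @param vol A [volume4d()] (or a [brain_mask()], written as 0/1).
#' @param path Output path; `gzip` appends/forces `.nii.gz`.
#' @param gzip Write gzip-compressed output.
#' @param datatype NIfTI on-disk datatype; `"double"` round-trips exactly.
#' @return The path written, invisibly.
#' @export
write_volume <- function(vol, path, gzip = grepl("\\.gz$", path),
                         datatype = "double") {
  if (inherits(vol, "brain_mask"))
    vol <- volume4d(array(as.numeric(vol$data), dim(vol$data)),
                    affine = vol$affine)
  if (!inherits(vol, "volume4d")) stop("'vol' must be a volume4d")
  path <- normalize_nii_path(path, gzip)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data <- vol$data
  if (dim(data)[4] == 1L) dim(data) <- dim(data)[1:3]
  img <- RNifti::asNifti(data)
  vd <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(vd, vol$tr)[seq_len(length(dim(data)))]
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  out <- tryCatch(RNifti::writeNifti(img, path, datatype = datatype),
                  error = function(e)
                    stop("cannot write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

normalize_nii_path <- function(path, gzip) {
  if (gzip) {
    if (!grepl("\\.nii\\.gz$", path))
      path <- paste0(sub("(\\.nii)?(\\.gz)?$", "", path), ".nii.gz")
  } else {
    if (!grepl("\\.nii$", path))
      path <- paste0(sub("(\\.nii)?(\\.gz)?$", "", path), ".nii")
  }
  path
}

#' Reshape a 4D volume to a frames-by-voxels matrix
#'
#' Column j holds the full time series of the j-th in-mask voxel; columns
#' are ordered by increasing linear voxel index (X fastest, then Y, then Z),
#' so the in-mask voxel with the smallest linear index maps to column 1.
#'
#' @param vol A [volume4d()].
#' @param mask A [brain_mask()] on the same grid.
#' @return A `ts_matrix` object: `values` (T x V), `voxel_index` (1-based
#'   linear indices), `tr`, `source_shape`.
#' @export
volume_to_matrix <- function(vol, mask) {
  stopifnot(inherits(vol, "volume4d"), inherits(mask, "brain_mask"))
  check_grid(dim(vol$data), vol$affine, dim(mask$data), mask$affine,
             "volume and mask")
  idx <- which(mask$data)
  if (length(idx) == 0L) stop("mask has no voxels set")
  d <- dim(vol$data)
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  ts_matrix(t(flat[idx, , drop = FALSE]), voxel_index = idx, tr = vol$tr,
            source_shape = d[1:3])
}

#' Construct a time-series matrix
#'
#' @param values T x V numeric matrix (frames by voxels).
#' @param voxel_index Strictly increasing 1-based linear grid indices, one
#'   per column.
#' @param tr Repetition time, seconds.
#' @param source_shape Integer (X, Y, Z) of the originating grid.
#' @return A `ts_matrix` object.
#' @export
ts_matrix <- function(values, voxel_index, tr, source_shape) {
  values <- as.matrix(values)
  voxel_index <- as.integer(voxel_index)
  if (ncol(values) != length(voxel_index))
    stop("one voxel index per column required")
  if (is.unsorted(voxel_index, strictly = TRUE))
    stop("'voxel_index' must be strictly increasing")
  structure(list(values = values, voxel_index = voxel_index,
                 tr = as.numeric(tr),
                 source_shape = as.integer(source_shape)),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %d frames x %d voxels, TR %g s, grid %s\n",
              nrow(x$values), ncol(x$values), x$tr,
              paste(x$source_shape, collapse = " x ")))
  invisible(x)
}

#' Place a time-series matrix back on the 3D/4D grid
#'
#' @param mat A `ts_matrix`.
#' @param mask The [brain_mask()] the matrix was extracted with.
#' @param template Optional [volume4d()] supplying affine/TR; defaults to
#'   the mask affine and the matrix TR.
#' @param fill Value written outside the mask (default 0; `NA` allowed).
#' @return A [volume4d()] with T = `nrow(mat$values)`.
#' @export
matrix_to_volume <- function(mat, mask, template = NULL, fill = 0) {
  stopifnot(inherits(mat, "ts_matrix"), inherits(mask, "brain_mask"))
  idx <- which(mask$data)
  if (!identical(as.integer(idx), mat$voxel_index))
    stop("matrix voxel_index does not match the mask")
  d3 <- dim(mask$data)
  nt <- nrow(mat$values)
  flat <- matrix(fill, nrow = prod(d3), ncol = nt)
  flat[idx, ] <- t(mat$values)
  data <- array(flat, dim = c(d3, nt))
  affine <- if (!is.null(template)) template$affine else mask$affine
  volume4d(data, affine = affine, tr = mat$tr)
}

#' Gaussian smoothing of each frame
#'
#' Separable Gaussian convolution per frame with zero padding at the
#' boundary; kernel width per axis given as full width at half maximum in
#' mm, converted to voxels through the affine voxel sizes.
#'
#' @param vol A [volume4d()].
#' @param fwhm Kernel FWHM in mm; scalar or length-3 (per axis). 0 disables
#'   smoothing along that axis.
#' @return Smoothed [volume4d()].
#' @export
smooth_volume <- function(vol, fwhm) {
  stopifnot(inherits(vol, "volume4d"))
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  if (any(fwhm < 0)) stop("'fwhm' must be non-negative")
  vd <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / vd
  data <- vol$data
  d <- dim(data)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    k <- gaussian_kernel_1d(sigma_vox[ax])
    data <- convolve_axis(data, k, ax)
  }
  volume4d(data, affine = vol$affine, tr = vol$tr, descrip = vol$descrip)
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Zero-padded 1D convolution along axis `ax` of a 4D array, via a banded
# matrix product on the unfolded array.
convolve_axis <- function(data, k, ax) {
  d <- dim(data)
  perm <- c(ax, setdiff(1:4, ax))
  x <- aperm(data, perm)
  n <- d[ax]
  m <- matrix(x, nrow = n)
  r <- (length(k) - 1L) / 2L
  cm <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    i <- seq_len(n)
    src <- i + off
    ok <- src >= 1L & src <= n
    cm[cbind(i[ok], src[ok])] <- cm[cbind(i[ok], src[ok])] + k[j]
  }
  y <- cm %*% m
  out <- array(y, dim = d[perm])
  aperm(out, order(perm))
}

#' World coordinates of voxel indices
#'
#' Voxel-center positions in mm: the affine applied to 0-based (i, j, k).
#'
#' @param affine 4x4 voxel-to-world transform.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk - 1, 1)
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

# 1-based linear index -> 1-based (i,j,k) for a given 3D shape.
index_to_ijk <- function(idx, shape) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% shape[1]
  j <- (idx0 %/% shape[1]) %% shape[2]
  k <- idx0 %/% (shape[1] * shape[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_index <- function(ijk, shape) {
  (ijk[, 3] - 1L) * shape[1] * shape[2] + (ijk[, 2] - 1L) * shape[1] + ijk[, 1]
}
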