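# Voxel-wise spontaneous-activity metrics: intensity normalization,
# time-series amplitude, ALFF/fALFF, regional homogeneity (Kendall's W),
# functional connectivity density (local / global / long-range, with
# bit-packed binarized connectivity), and functional connectivity strength.

#' Neighborhood scheme for voxel-cluster metrics
#'
#' @param kind `"face"` (6 neighbors), `"edge"` (18) or `"vertex"` (26).
#' @return A `neighbor_scheme` with the offset list and `k_total`
#'   (neighbors + seed: 7, 19 or 27).
#' @export
neighbor_scheme <- function(kind = c("vertex", "face", "edge")) {
  kind <- match.arg(kind)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  offs <- switch(kind,
                 face = g[nz == 1, , drop = FALSE],
                 edge = g[nz >= 1 & nz <= 2, , drop = FALSE],
                 vertex = g[nz >= 1, , drop = FALSE])
  structure(list(kind = kind, offsets = unname(offs),
                 k_total = nrow(offs) + 1L),
            class = "neighbor_scheme")
}

#' Intensity normalization of a metric map
#'
#' Mean mode divides by the in-mask mean (in-mask mean becomes 1); z-score
#' mode subtracts the in-mask mean and divides by the in-mask standard
#' deviation (mean 0, sd 1).
#'
#' @param map A single-frame [volume4d()] metric map.
#' @param mask A [brain_mask()].
#' @param mode `"mean"` or `"zscore"`.
#' @return Normalized [volume4d()].
#' @export
normalize_map <- function(map, mask, mode = c("zscore", "mean")) {
  mode <- match.arg(mode)
  mat <- volume_to_matrix(map, mask)
  v <- mat$values[1, ]
  if (mode == "mean") {
    mu <- mean(v)
    if (abs(mu) < .Machine$double.eps)
      stop("mean normalization undefined: in-mask mean is 0")
    v <- v / mu
  } else {
    sdv <- stats::sd(v)
    if (sdv == 0) stop("z-score normalization undefined: in-mask sd is 0")
    v <- (v - mean(v)) / sdv
  }
  mat$values[1, ] <- v
  matrix_to_volume(mat, mask, template = map)
}

#' Amplitude of time series (mean and standard deviation)
#'
#' Per voxel, AM_mean = mean(|x - xbar|) and AM_std = the corrected (N - 1)
#' sample standard deviation of the mean-subtracted series.
#'
#' @param mat A `ts_matrix` with N >= 2 frames.
#' @param mask Optional [brain_mask()]; if given, results are returned as
#'   map volumes, otherwise as vectors.
#' @return List with `am_mean` and `am_std` (vectors, or [volume4d()] maps
#'   when `mask` is supplied).
#' @export
amplitude <- function(mat, mask = NULL) {
  stopifnot(inherits(mat, "ts_matrix"))
  Y <- mat$values
  n <- nrow(Y)
  if (n < 2L) stop("amplitude requires at least 2 frames")
  C <- sweep(Y, 2, colMeans(Y))
  am_mean <- colMeans(abs(C))
  am_std <- sqrt(colSums(C^2) / (n - 1))
  wrap_maps(list(am_mean = am_mean, am_std = am_std), mat, mask)
}

wrap_maps <- function(vals, mat, mask) {
  if (is.null(mask)) return(vals)
  lapply(vals, function(v)
    matrix_to_volume(ts_matrix(matrix(v, nrow = 1), mat$voxel_index,
                               tr = mat$tr, mat$source_shape), mask))
}

#' Amplitude of low-frequency fluctuation (ALFF and fALFF)
#'
#' Per voxel, the one-sided amplitude spectrum a_k = sqrt(F_k conj(F_k) / L)
#' is computed from the discrete Fourier transform F of the (unfiltered)
#' series of length L. ALFF is the mean of a_k over the bins whose frequency
#' falls in `band`; fALFF is the sum of in-band a_k divided by the sum over
#' all bins with 0 < f <= Nyquist. Voxels with zero total spectral amplitude
#' get fALFF 0.
#'
#' @param mat A `ts_matrix` (unfiltered input is intended).
#' @param band Length-2 band in Hz.
#' @param mask Optional [brain_mask()] for map output.
#' @return List with `alff` and `falff` (vectors or maps).
#' @export
alff_falff <- function(mat, band = c(0.01, 0.08), mask = NULL) {
  stopifnot(inherits(mat, "ts_matrix"))
  Y <- mat$values
  nt <- nrow(Y)
  f <- bin_frequencies(nt, mat$tr)
  pos <- seq_len(floor(nt / 2) + 1L)[-1L]  # 0 < f <= Nyquist, one-sided
  inband <- pos[f[pos] >= band[1] - 1e-12 & f[pos] <= band[2] + 1e-12]
  if (length(inband) == 0L)
    stop(sprintf(
      "no frequency bins inside [%g, %g] Hz at resolution %g Hz",
      band[1], band[2], 1 / (nt * mat$tr)))
  Fh <- stats::mvfft(Y)
  amp <- sqrt(Re(Fh * Conj(Fh)) / nt)
  alff <- colMeans(amp[inband, , drop = FALSE])
  denom <- colSums(amp[pos, , drop = FALSE])
  num <- colSums(amp[inband, , drop = FALSE])
  falff <- ifelse(denom > 0, num / denom, 0)
  wrap_maps(list(alff = alff, falff = falff), mat, mask)
}

# Column index (into the ts_matrix) of each in-mask neighbor of each voxel,
# as a list. Voxel positions come from the matrix's voxel_index.
neighbor_columns <- function(voxel_index, shape, scheme) {
  col_of <- integer(prod(shape))
  col_of[voxel_index] <- seq_along(voxel_index)
  ijk <- index_to_ijk(voxel_index, shape)
  offs <- scheme$offsets
  nb <- vector("list", length(voxel_index))
  for (o in seq_len(nrow(offs))) {
    n <- sweep(ijk, 2, offs[o, ], "+")
    ok <- n[, 1] >= 1 & n[, 1] <= shape[1] &
          n[, 2] >= 1 & n[, 2] <= shape[2] &
          n[, 3] >= 1 & n[, 3] <= shape[3]
    lin <- rep(0L, length(voxel_index))
    lin[ok] <- col_of[ijk_to_index(n[ok, , drop = FALSE], shape)]
    hit <- which(lin > 0L)
    for (v in hit) nb[[v]] <- c(nb[[v]], lin[v])
  }
  nb
}

#' Regional homogeneity (Kendall's coefficient of concordance)
#'
#' For each in-mask voxel, Kendall's W over the seed series and its in-mask
#' neighbors:
#'   W = (sum_i R_i^2 - n Rbar^2) / ((1/12) K^2 (n^3 - n))
#' where K is the number of concordant series (seed + neighbors; 7, 19 or
#' 27 in the interior), R_i the sum of the K series' ranks at frame i, and
#' n the number of frames. Ranking uses midranks for ties, with no tie
#' correction in the denominator. At the mask boundary K shrinks to the
#' available members. Fully constant neighborhoods get W = 0.
#'
#' @param mat A `ts_matrix`.
#' @param mask The [brain_mask()] the matrix was extracted with.
#' @param scheme A [neighbor_scheme()] (default vertex / 27).
#' @return A single-frame [volume4d()] map of W in `[0, 1]`.
#' @export
reho <- function(mat, mask, scheme = neighbor_scheme("vertex")) {
  stopifnot(inherits(mat, "ts_matrix"))
  Y <- mat$values
  n <- nrow(Y)
  if (n < 2L) stop("ReHo requires at least 2 frames")
  ranks <- apply(Y, 2, rank)     # midranks for ties
  nb <- neighbor_columns(mat$voxel_index, mat$source_shape, scheme)
  w <- vapply(seq_len(ncol(Y)), function(v) {
    members <- c(v, nb[[v]])
    kendall_w_from_ranks(ranks[, members, drop = FALSE])
  }, numeric(1))
  if (any(w == 0))
    if (any(apply(Y, 2, stats::sd) == 0))
      warning("constant neighborhoods encountered; W set to 0 there")
  wrap_maps(list(reho = w), mat, mask)$reho
}

# Kendall's W from an n x K matrix of per-series ranks.
kendall_w_from_ranks <- function(R) {
  n <- nrow(R)
  K <- ncol(R)
  Ri <- rowSums(R)
  num <- sum(Ri^2) - n * mean(Ri)^2
  den <- K^2 * (n^3 - n) / 12
  if (num <= 0) return(0)
  min(1, num / den)
}

# --- functional connectivity density --------------------------------------

# Pack one logical vector into a raw (bit) vector.
pack_row <- function(x) packBits(c(x, rep(FALSE, (-length(x)) %% 8L)))

unpack_row <- function(r, n) as.logical(rawToBits(r))[seq_len(n)]

#' Bit-packed binarized connectivity store
#'
#' Thresholds a correlation matrix at `r_threshold` (strict inequality) and
#' stores each row as packed bits, 1 bit per pair; the store occupies
#' 1/32 of the bytes of a dense float32 (4-byte) binarized matrix.
#'
#' @param cmat V x V correlation matrix.
#' @param r_threshold Correlation threshold; entries strictly greater are 1.
#' @return A `packed_adjacency`: list of raw rows, `n`, `bytes`,
#'   `float_bytes`.
#' @export
pack_adjacency <- function(cmat, r_threshold) {
  n <- nrow(cmat)
  rows <- lapply(seq_len(n), function(i) {
    x <- cmat[i, ] > r_threshold
    x[i] <- FALSE
    pack_row(x)
  })
  structure(list(rows = rows, n = n,
                 bytes = sum(vapply(rows, length, integer(1))) + 0,
                 float_bytes = as.numeric(n) * n * 4),
            class = "packed_adjacency")
}

#' @export
print.packed_adjacency <- function(x, ...) {
  cat(sprintf("<packed_adjacency> %d x %d, %d bytes (float32 dense: %d)\n",
              x$n, x$n, x$bytes, x$float_bytes))
  invisible(x)
}

adjacency_row <- function(adj, i) unpack_row(adj$rows[[i]], adj$n)

#' Functional connectivity density (local, global, long-range)
#'
#' For each in-mask seed voxel: gFCD is the number of other voxels whose
#' Pearson correlation with the seed strictly exceeds `r_threshold`; lFCD is
#' the size (seed excluded) of the region grown from the seed by repeatedly
#' adding voxels that are spatially adjacent (under `scheme`) to a current
#' member and supra-threshold correlated with the seed; lrFCD = gFCD - lFCD.
#' The binarized connectivity is held bit-packed (1 bit per pair) by
#' default; `packed = FALSE` runs a dense reference path with identical
#' outputs.
#'
#' @param mat A `ts_matrix`.
#' @param mask The matching [brain_mask()].
#' @param r_threshold Correlation threshold in (0, 1) (default 0.6).
#' @param scheme A [neighbor_scheme()]; default vertex-connected.
#' @param packed Use the bit-packed adjacency store (default TRUE).
#' @return List of three single-frame [volume4d()] maps: `lfcd`, `gfcd`,
#'   `lrfcd`.
#' @export
fcd <- function(mat, mask, r_threshold = 0.6,
                scheme = neighbor_scheme("vertex"), packed = TRUE) {
  stopifnot(inherits(mat, "ts_matrix"))
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("'r_threshold' must be in (0, 1)")
  Y <- mat$values
  nv <- ncol(Y)
  if (nv < 2L) stop("FCD requires at least 2 voxels")
  sdv <- apply(Y, 2, stats::sd)
  if (any(sdv == 0))
    warning("zero-variance voxels present; their FCD metrics are 0")
  cmat <- safe_cor(Y, sdv)
  nb <- neighbor_columns(mat$voxel_index, mat$source_shape, scheme)
  if (packed) {
    adj <- pack_adjacency(cmat, r_threshold)
    row_fun <- function(i) adjacency_row(adj, i)
  } else {
    row_fun <- function(i) {
      x <- cmat[i, ] > r_threshold
      x[i] <- FALSE
      x
    }
  }
  gfcd <- numeric(nv)
  lfcd <- numeric(nv)
  for (i in seq_len(nv)) {
    conn <- row_fun(i)
    gfcd[i] <- sum(conn)
    lfcd[i] <- region_grow_count(i, conn, nb)
  }
  lrfcd <- gfcd - lfcd
  wrap_maps(list(lfcd = lfcd, gfcd = gfcd, lrfcd = lrfcd), mat, mask)
}

# Correlation with zero-variance columns mapped to 0 rather than NA.
safe_cor <- function(Y, sdv = apply(Y, 2, stats::sd)) {
  ok <- sdv > 0
  cmat <- matrix(0, ncol(Y), ncol(Y))
  if (any(ok)) cmat[ok, ok] <- stats::cor(Y[, ok, drop = FALSE])
  diag(cmat) <- 1
  cmat
}

# Breadth-first region growth from `seed`: a voxel joins if spatially
# adjacent to a member and supra-threshold correlated with the seed
# (conn[v] is that indicator). Returns the member count excluding the seed.
region_grow_count <- function(seed, conn, nb) {
  member <- logical(length(conn))
  member[seed] <- TRUE
  frontier <- seed
  count <- 0L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      cand <- nb[[v]]
      cand <- cand[!member[cand] & conn[cand]]
      if (length(cand) > 0L) {
        member[cand] <- TRUE
        nxt <- c(nxt, cand)
        count <- count + length(cand)
      }
    }
    frontier <- nxt
  }
  count
}

#' Functional connectivity strength
#'
#' Voxel-wise Pearson correlations with all other in-mask voxels are
#' Fisher-z transformed; the FCS of a seed is the sum of z values strictly
#' above `threshold` divided by V - 1 (seed excluded).
#'
#' @param mat A `ts_matrix`.
#' @param mask Optional [brain_mask()] for map output.
#' @param threshold Threshold on the Fisher-z scale (default 0.25, about
#'   r = 0.245).
#' @return FCS vector, or a [volume4d()] map when `mask` is supplied.
#' @export
fcs <- function(mat, mask = NULL, threshold = 0.25) {
  stopifnot(inherits(mat, "ts_matrix"))
  Y <- mat$values
  nv <- ncol(Y)
  if (nv < 2L) stop("FCS requires at least 2 voxels")
  sdv <- apply(Y, 2, stats::sd)
  if (any(sdv == 0))
    warning("zero-variance voxels present; their FCS is 0")
  cmat <- safe_cor(Y, sdv)
  diag(cmat) <- 0
  z <- fisher_z(cmat)
  z[z <= threshold] <- 0
  diag(z) <- 0
  out <- rowSums(z) / (nv - 1)
  out[sdv == 0] <- 0
  if (is.null(mask)) return(out)
  wrap_maps(list(fcs = out), mat, mask)$fcs
}
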