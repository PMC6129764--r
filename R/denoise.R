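# Nuisance regression, motion scrubbing and ideal band-pass filtering.
#
# The regression design follows the tissue + 24-parameter motion model:
#   X = [ones, trends, T, T^2, T', T'^2, T_{t-1}, T^2_{t-1},
#               R, R^2, R', R'^2, R_{t-1}, R^2_{t-1}]
# with T = (WM, CSF[, GS]) mean tissue series and R the six realignment
# parameters. Derivatives are backward differences with a leading zero;
# lags shift by one frame with a leading zero; squared blocks square every
# base/variant column elementwise.

#' Tissue mean time series
#'
#' @param wm White-matter mean series (length T).
#' @param csf Cerebrospinal-fluid mean series (length T).
#' @param gs Optional global-signal series (length T).
#' @return A `tissue_signals` object.
#' @export
tissue_signals <- function(wm, csf, gs = NULL) {
  n <- length(wm)
  if (length(csf) != n || (!is.null(gs) && length(gs) != n))
    stop("tissue series must all have the same length")
  structure(list(wm = as.numeric(wm), csf = as.numeric(csf),
                 gs = if (!is.null(gs)) as.numeric(gs)),
            class = "tissue_signals")
}

#' Extract tissue mean series from a volume
#'
#' @param vol A [volume4d()].
#' @param wm_mask,csf_mask [brain_mask()] objects for white matter and CSF.
#' @param gs_mask Optional whole-brain mask for the global signal.
#' @return A [tissue_signals()] object.
#' @export
extract_tissue_signals <- function(vol, wm_mask, csf_mask, gs_mask = NULL) {
  ms <- function(m) rowMeans(volume_to_matrix(vol, m)$values)
  tissue_signals(wm = ms(wm_mask), csf = ms(csf_mask),
                 gs = if (!is.null(gs_mask)) ms(gs_mask))
}

backward_diff <- function(x) c(0, diff(x))
lag_one <- function(x) c(0, x[-length(x)])

#' Build the nuisance regression design
#'
#' Assembles the design matrix from optional blocks: intercept (always),
#' linear and quadratic trends, tissue means (WM, CSF, optionally GS), the
#' six motion parameters, plus per-block first derivatives (backward
#' difference, zero at frame 1), 1-frame lags (zero at frame 1), and
#' elementwise squares of every base/variant column. With all blocks and GS
#' on the design has 1 + 2 + 3*6 + 6*6 = 57 columns.
#'
#' @param tissue A [tissue_signals()] or `NULL` to omit the tissue block.
#' @param motion A [motion_params()] or `NULL` to omit the motion block.
#' @param n_frames Required if both `tissue` and `motion` are `NULL`.
#' @param trends Include linear + quadratic trend columns.
#' @param gs Include the global-signal column (requires `tissue$gs`).
#' @param squares Include squared copies of every base/variant column.
#' @param derivatives Include first-derivative variants.
#' @param lags Include 1-frame-lagged variants.
#' @return A `nuisance_design`: `matrix` (T x p), `labels`, `options`.
#' @export
build_design <- function(tissue = NULL, motion = NULL, n_frames = NULL,
                         trends = TRUE, gs = !is.null(tissue$gs),
                         squares = TRUE, derivatives = TRUE, lags = TRUE) {
  nt <- if (!is.null(tissue)) length(tissue$wm)
        else if (!is.null(motion)) nrow(motion$values)
        else n_frames
  if (is.null(nt)) stop("cannot determine the number of frames")
  if (gs && (is.null(tissue) || is.null(tissue$gs)))
    stop("gs = TRUE requires a global-signal series in 'tissue'")
  if (!is.null(motion) && nrow(motion$values) != nt)
    stop("motion trace length does not match tissue series length")

  cols <- list(ones = rep(1, nt))
  if (trends) {
    u <- seq_len(nt) / nt
    cols$trend_linear <- u
    cols$trend_quadratic <- u^2
  }

  base <- list()
  if (!is.null(tissue)) {
    base$wm <- tissue$wm
    base$csf <- tissue$csf
    if (gs) base$gs <- tissue$gs
  }
  if (!is.null(motion))
    for (j in 1:6) base[[colnames(motion$values)[j]]] <- motion$values[, j]

  variant_block <- function(b, fun, suffix) {
    out <- lapply(b, fun)
    names(out) <- paste0(names(b), suffix)
    out
  }
  if (length(base) > 0L) {
    variants <- base
    if (derivatives)
      variants <- c(variants, variant_block(base, backward_diff, "_deriv"))
    if (lags)
      variants <- c(variants, variant_block(base, lag_one, "_lag1"))
    if (squares)
      variants <- c(variants,
                    variant_block(variants, function(x) x^2, "_sq"))
    cols <- c(cols, variants)
  } else {
    warning("no nuisance blocks enabled; design is intercept",
            if (trends) " + trends" else "", " only")
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(matrix = X, labels = names(cols),
                 options = list(trends = trends, gs = gs, squares = squares,
                                derivatives = derivatives, lags = lags)),
            class = "nuisance_design")
}

#' Censor plan from framewise displacement
#'
#' @param fd Length-T framewise displacement, mm.
#' @param threshold FD threshold in mm; frames with FD > threshold are
#'   removed.
#' @return A `censor_plan`: `fd`, `threshold`, `kept`, `removed` (1-based
#'   frame indices).
#' @export
censor_plan <- function(fd, threshold = 0.5) {
  fd <- as.numeric(fd)
  removed <- which(fd > threshold)
  structure(list(fd = fd, threshold = threshold,
                 kept = setdiff(seq_along(fd), removed), removed = removed),
            class = "censor_plan")
}

#' Remove censored frames from a time-series matrix
#'
#' @param mat A `ts_matrix`.
#' @param plan A [censor_plan()] of matching length.
#' @param min_frames_frac Error if fewer than this fraction of frames
#'   survive (default 0.5).
#' @return List with the scrubbed `ts_matrix` (kept frames only) and the
#'   plan.
#' @export
scrub <- function(mat, plan, min_frames_frac = 0.5) {
  stopifnot(inherits(mat, "ts_matrix"), inherits(plan, "censor_plan"))
  nt <- nrow(mat$values)
  if (length(plan$fd) != nt)
    stop("censor plan length does not match the matrix")
  if (length(plan$kept) < min_frames_frac * nt)
    stop(sprintf("too few frames retained after scrubbing (%d of %d)",
                 length(plan$kept), nt))
  out <- mat
  out$values <- mat$values[plan$kept, , drop = FALSE]
  list(matrix = out, plan = plan)
}

# Moore-Penrose pseudoinverse via SVD; used when the design is
# rank-deficient.
pinv <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps * max(s$d)
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Regress nuisance signals out of voxel time series
#'
#' Per voxel, the least-squares fit of the series on the design is computed
#' over the kept frames of `plan` (all frames when `plan` is `NULL`), and
#' the fitted values are subtracted everywhere so the returned residual
#' series is unbroken in time.
#'
#' @param mat A `ts_matrix` (all frames).
#' @param design A [build_design()] result with `nrow == nrow(mat$values)`.
#' @param plan Optional [censor_plan()]; betas are estimated on kept frames
#'   only.
#' @return A `ts_matrix` of residuals, same dimensions as the input.
#' @export
regress_nuisance <- function(mat, design, plan = NULL) {
  stopifnot(inherits(mat, "ts_matrix"), inherits(design, "nuisance_design"))
  X <- design$matrix
  Y <- mat$values
  if (nrow(X) != nrow(Y)) stop("design rows must equal matrix frames")
  if (!all(is.finite(X))) {
    bad <- design$labels[!apply(is.finite(X), 2, all)]
    stop("non-finite design columns: ", paste(bad, collapse = ", "))
  }
  if (!all(is.finite(Y)))
    stop("non-finite voxel series at columns: ",
         paste(utils::head(which(!apply(is.finite(Y), 2, all)), 10),
               collapse = ", "))
  keep <- if (is.null(plan)) seq_len(nrow(Y)) else plan$kept
  # scale columns to unit norm so rank detection is not dominated by the
  # very different magnitudes of e.g. squared-derivative blocks
  scale <- sqrt(colSums(X[keep, , drop = FALSE]^2))
  scale[scale == 0] <- 1
  Xs <- sweep(X, 2, scale, "/")
  Xk <- Xs[keep, , drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    warning("rank-deficient nuisance design; using a pseudoinverse fit")
    beta <- pinv(Xk) %*% Y[keep, , drop = FALSE]
  } else {
    beta <- qr.coef(qrX, Y[keep, , drop = FALSE])
  }
  out <- mat
  out$values <- Y - Xs %*% beta
  out
}

#' Ideal band-pass filter with mirrored extension
#'
#' Each series is extended to length 2T by appending its time reverse,
#' transformed with the FFT, frequency bins with `low <= f <= high` retained
#' (both signs) and all others zeroed, inverse-transformed, and the first T
#' samples returned. The mirrored extension removes the wrap-around
#' discontinuity of the plain periodic transform.
#'
#' @param mat A `ts_matrix`.
#' @param low,high Pass-band edges in Hz; `0 <= low < high <= 1/(2 tr)`.
#'   `low = 0` retains the DC bin.
#' @return Filtered `ts_matrix`.
#' @export
bandpass <- function(mat, low = 0.01, high = 0.08) {
  stopifnot(inherits(mat, "ts_matrix"))
  nyq <- 1 / (2 * mat$tr)
  if (low < 0 || high <= low || high > nyq + 1e-12)
    stop(sprintf("band [%g, %g] Hz must satisfy 0 <= low < high <= %g",
                 low, high, nyq))
  Y <- mat$values
  nt <- nrow(Y)
  ext <- rbind(Y, Y[nt:1, , drop = FALSE])
  n2 <- 2L * nt
  f <- bin_frequencies(n2, mat$tr)
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  Fh <- stats::mvfft(ext)
  Fh[!keep, ] <- 0
  flt <- Re(stats::mvfft(Fh, inverse = TRUE)) / n2
  out <- mat
  out$values <- flt[seq_len(nt), , drop = FALSE]
  out
}

# Physical frequency (Hz) of each DFT bin of an n-point series sampled at
# interval tr: bin k (0-based) maps to min(k, n-k) / (n * tr).
bin_frequencies <- function(n, tr) {
  k <- 0:(n - 1)
  pmin(k, n - k) / (n * tr)
}

#' One-shot denoising of a 4D volume
#'
#' Runs the full stage order: scrub (identify frames to censor), nuisance
#' regression (betas fit on kept frames, residuals everywhere), then ideal
#' band-pass filtering. Censored frames remain in the output so the filter
#' sees an unbroken series; drop them afterwards with [scrub()] if needed.
#'
#' @param vol A [volume4d()].
#' @param mask A [brain_mask()].
#' @param design A [build_design()] result (or `NULL` to skip regression).
#' @param plan Optional [censor_plan()].
#' @param band Length-2 pass band in Hz, or `NULL` to skip filtering.
#' @param order `"regress_then_filter"` (default) or
#'   `"filter_then_regress"`.
#' @return A `ts_matrix` of denoised series (all frames).
#' @export
denoise <- function(vol, mask, design = NULL, plan = NULL,
                    band = c(0.01, 0.08),
                    order = c("regress_then_filter",
                              "filter_then_regress")) {
  order <- match.arg(order)
  mat <- volume_to_matrix(vol, mask)
  reg <- function(m) if (is.null(design)) m
                     else regress_nuisance(m, design, plan)
  flt <- function(m) if (is.null(band)) m
                     else bandpass(m, band[1], band[2])
  if (order == "regress_then_filter") flt(reg(mat)) else reg(flt(mat))
}
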