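# Synthetic fixtures: phantoms with planted spectral content, motion traces,
# and labelled atlases. All randomness flows through one explicit seed; the
# caller's global random state is saved and restored.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specify a synthetic phantom
#'
#' A phantom is a baseline intensity plus, per component, a waveform added
#' to all voxels of a region (shared across the region) and/or white noise
#' (independent per voxel). Regions are logical 3D arrays or `"global"`.
#'
#' @param dims Integer (X, Y, Z) grid.
#' @param n_frames Number of time frames T.
#' @param tr Repetition time, seconds.
#' @param components List of components; each is a list with `region`
#'   (`"global"` or a logical array) and `waveform`, one of
#'   [wf_sinusoid()], [wf_drift()], [wf_noise()].
#' @param baseline Baseline intensity added everywhere.
#' @param seed Integer seed; fully determines the output.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims, n_frames, tr = 2, components = list(),
                         baseline = 0, seed = 1) {
  nyq <- 1 / (2 * tr)
  for (cm in components) {
    wf <- cm$waveform
    if (identical(wf$kind, "sinusoid") && wf$freq >= nyq)
      stop(sprintf("sinusoid frequency %g Hz is at or above Nyquist %g Hz",
                   wf$freq, nyq))
  }
  structure(list(dims = as.integer(dims), n_frames = as.integer(n_frames),
                 tr = tr, components = components, baseline = baseline,
                 seed = seed),
            class = "phantom_spec")
}

#' Sinusoidal waveform component
#' @param freq Frequency in Hz (must be below Nyquist).
#' @param amplitude Peak amplitude.
#' @param phase Phase in radians.
#' @export
wf_sinusoid <- function(freq, amplitude = 1, phase = 0)
  list(kind = "sinusoid", freq = freq, amplitude = amplitude, phase = phase)

#' Polynomial drift waveform component
#' @param order Polynomial order (1 = linear).
#' @param amplitude Value reached at the last frame.
#' @export
wf_drift <- function(order = 1, amplitude = 1)
  list(kind = "drift", order = order, amplitude = amplitude)

#' White-noise waveform component (independent per voxel)
#' @param sd Standard deviation.
#' @export
wf_noise <- function(sd = 1) list(kind = "noise", sd = sd)

#' Generate a phantom volume
#'
#' @param spec A [phantom_spec()].
#' @return A [volume4d()] with 3 mm isotropic voxels.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  nt <- spec$n_frames
  nvox <- prod(d)
  with_seed(spec$seed, {
    flat <- matrix(spec$baseline, nrow = nvox, ncol = nt)
    t_sec <- (seq_len(nt) - 1) * spec$tr
    for (cm in spec$components) {
      region <- cm$region
      idx <- if (identical(region, "global")) seq_len(nvox)
             else which(as.logical(region))
      wf <- cm$waveform
      if (wf$kind == "sinusoid") {
        w <- wf$amplitude * sin(2 * pi * wf$freq * t_sec + wf$phase)
        flat[idx, ] <- flat[idx, ] + rep(w, each = length(idx))
      } else if (wf$kind == "drift") {
        u <- if (nt > 1) (seq_len(nt) - 1) / (nt - 1) else 0
        w <- wf$amplitude * u^wf$order
        flat[idx, ] <- flat[idx, ] + rep(w, each = length(idx))
      } else if (wf$kind == "noise") {
        if (wf$sd > 0)
          flat[idx, ] <- flat[idx, ] +
            matrix(stats::rnorm(length(idx) * nt, sd = wf$sd),
                   nrow = length(idx))
      } else stop("unknown waveform kind: ", wf$kind)
    }
    volume4d(array(flat, dim = c(d, nt)),
             affine = diag(c(3, 3, 3, 1)), tr = spec$tr)
  })
}

#' Generate a realignment-style motion trace
#'
#' Six columns (x, y, z translations in mm; pitch, yaw, roll rotations in
#' radians): a seeded random walk of per-frame increments with standard
#' deviation `drift_sd`, plus step events.
#'
#' @param n_frames Number of frames.
#' @param events List of `list(frame, axis, delta)`: from `frame` onward the
#'   parameter `axis` (1-6) is offset by `delta`.
#' @param drift_sd Per-frame random-walk increment sd (same units as the
#'   parameter). 0 gives a deterministic trace.
#' @param seed Integer seed.
#' @return A `motion_params` object wrapping a T x 6 matrix.
#' @export
generate_motion <- function(n_frames, events = list(), drift_sd = 0,
                            seed = 1) {
  n_frames <- as.integer(n_frames)
  with_seed(seed, {
    m <- matrix(0, n_frames, 6)
    if (drift_sd > 0)
      m <- apply(matrix(stats::rnorm(n_frames * 6, sd = drift_sd),
                        n_frames, 6), 2, cumsum)
    for (ev in events) {
      if (!(ev$axis %in% 1:6))
        stop("motion event axis must be in 1..6")
      if (ev$frame < 1 || ev$frame > n_frames)
        stop("motion event frame out of range")
      m[ev$frame:n_frames, ev$axis] <- m[ev$frame:n_frames, ev$axis] +
        ev$delta
    }
    motion_params(m)
  })
}

#' Construct motion parameters
#'
#' @param values T x 6 matrix: translations x, y, z in mm, then rotations
#'   pitch, yaw, roll in radians.
#' @param rotation_units `"radians"` (realignment convention) or
#'   `"degrees"` (converted on input).
#' @return A `motion_params` object.
#' @export
motion_params <- function(values, rotation_units = c("radians", "degrees")) {
  rotation_units <- match.arg(rotation_units)
  values <- as.matrix(values)
  if (ncol(values) != 6L) stop("motion parameters must have 6 columns")
  if (!all(is.finite(values))) stop("motion parameters must be finite")
  if (rotation_units == "degrees")
    values[, 4:6] <- values[, 4:6] * pi / 180
  colnames(values) <- c("x", "y", "z", "pitch", "yaw", "roll")
  structure(list(values = values), class = "motion_params")
}

#' Read a realignment parameter text file
#'
#' Whitespace-delimited, T rows x 6 columns, translations then rotations.
#'
#' @param path File path.
#' @param rotation_units Units of columns 4-6 in the file.
#' @return A [motion_params()] object.
#' @export
read_motion <- function(path, rotation_units = "radians") {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_params(m, rotation_units = rotation_units)
}

#' Write a realignment parameter text file
#' @param motion A [motion_params()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion$values, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a labelled ROI atlas of connected blobs
#'
#' Plants `n_rois` seed voxels and grows each blob by face-connected
#' accretion until it has at least `min_size` voxels; blobs are pairwise
#' disjoint and labelled 1..n_rois.
#'
#' @param dims Integer (X, Y, Z).
#' @param n_rois Number of regions.
#' @param min_size Minimum voxels per region.
#' @param seed Integer seed.
#' @return An [roi_atlas()] object.
#' @export
generate_atlas <- function(dims, n_rois, min_size = 5, seed = 1) {
  dims <- as.integer(dims)
  if (n_rois * min_size > prod(dims))
    stop("cannot pack ", n_rois, " regions of ", min_size,
         " voxels into the grid")
  with_seed(seed, {
    lab <- array(0L, dim = dims)
    nvox <- prod(dims)
    starts <- sample.int(nvox, n_rois)
    lab[starts] <- seq_len(n_rois)
    sizes <- rep(1L, n_rois)
    offs <- face_offsets()
    # round-robin accretion keeps blob sizes balanced
    repeat {
      if (all(sizes >= min_size)) break
      grew <- FALSE
      for (r in seq_len(n_rois)) {
        if (sizes[r] >= min_size) next
        members <- which(lab == r)
        cand <- neighbor_indices(members, dims, offs)
        cand <- cand[lab[cand] == 0L]
        if (length(cand) == 0L) next
        pick <- cand[sample.int(length(cand), 1L)]
        lab[pick] <- r
        sizes[r] <- sizes[r] + 1L
        grew <- TRUE
      }
      if (!grew)
        stop("atlas generation stalled: regions cannot grow to min_size")
    }
    tab <- data.frame(index = seq_len(n_rois),
                      label = sprintf("roi%02d", seq_len(n_rois)),
                      stringsAsFactors = FALSE)
    roi_atlas(lab, affine = diag(c(3, 3, 3, 1)), table = tab)
  })
}

face_offsets <- function() {
  rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
        c(0, 0, -1), c(0, 0, 1))
}

# All distinct in-grid neighbors (by the given offsets) of a set of linear
# indices.
neighbor_indices <- function(idx, dims, offs) {
  ijk <- index_to_ijk(idx, dims)
  out <- integer(0)
  for (o in seq_len(nrow(offs))) {
    n <- sweep(ijk, 2, offs[o, ], "+")
    ok <- n[, 1] >= 1 & n[, 1] <= dims[1] &
          n[, 2] >= 1 & n[, 2] <= dims[2] &
          n[, 3] >= 1 & n[, 3] <= dims[3]
    if (any(ok)) out <- c(out, ijk_to_index(n[ok, , drop = FALSE], dims))
  }
  setdiff(unique(out), idx)
}
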