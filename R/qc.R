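# Head-motion quality control and temporal signal-to-noise masking.

#' Framewise displacement
#'
#' Per frame, the sum of absolute changes of the six realignment parameters
#' between consecutive frames, with rotations converted to arc length on a
#' sphere of `head_radius` mm (Power-style FD). The first frame has FD 0.
#'
#' @param motion A [motion_params()] object.
#' @param head_radius Sphere radius in mm for the rotation-to-mm conversion
#'   (default 50).
#' @return Length-T numeric vector, mm.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  stopifnot(inherits(motion, "motion_params"))
  m <- motion$values
  if (nrow(m) < 2L) stop("at least 2 frames are required for FD")
  d <- abs(diff(m))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

# Combined rotation angle of (pitch, yaw, roll), radians: the Van Dijk
# composite arccos((cos p cos y + cos p cos r + cos y cos r +
#                   sin p sin y sin r - 1)/2).
euler_angle <- function(p, y, r) {
  arg <- (cos(p) * cos(y) + cos(p) * cos(r) + cos(y) * cos(r) +
            sin(p) * sin(y) * sin(r) - 1) / 2
  acos(pmin(1, pmax(-1, arg)))
}

#' Head-motion summary statistics
#'
#' Per-subject exclusion criteria: maximum absolute translation (mm) and
#' rotation (degrees); mean and maximum head displacement, where per-frame
#' displacement is the root-mean-square of the three translations
#' sqrt(x^2 + y^2 + z^2); the number of micro displacements, i.e.
#' inter-frame displacement changes exceeding `micro_threshold`; the mean
#' absolute composite Euler rotation angle (degrees); mean FD; and the count
#' of frames with FD above `fd_threshold`.
#'
#' @param motion A [motion_params()] object.
#' @param fd_threshold FD threshold in mm (default 0.5).
#' @param micro_threshold Micro-displacement threshold in mm (default 0.1).
#' @param head_radius Radius for the FD rotation conversion, mm.
#' @return A one-row `data.frame` of summary fields.
#' @export
motion_summary <- function(motion, fd_threshold = 0.5,
                           micro_threshold = 0.1, head_radius = 50) {
  stopifnot(inherits(motion, "motion_params"))
  m <- motion$values
  disp <- sqrt(rowSums(m[, 1:3, drop = FALSE]^2))
  fd <- framewise_displacement(motion, head_radius)
  ea <- euler_angle(m[, 4], m[, 5], m[, 6])
  data.frame(
    max_abs_translation = max(abs(m[, 1:3])),
    max_abs_rotation = max(abs(m[, 4:6])) * 180 / pi,
    mean_rms_displacement = mean(disp),
    max_displacement = max(disp),
    n_micro_displacements = sum(abs(diff(disp)) > micro_threshold),
    mean_abs_euler_angle = mean(abs(ea)) * 180 / pi,
    mean_fd = mean(fd),
    n_fd_above = sum(fd > fd_threshold),
    fd_threshold = fd_threshold
  )
}

#' Append per-subject motion summaries to a QC table
#'
#' @param summaries Named list of [motion_summary()] rows (names = subject
#'   tokens).
#' @param path CSV path; created with a header if absent, appended
#'   otherwise.
#' @return The path, invisibly.
#' @export
write_qc_table <- function(summaries, path) {
  tab <- do.call(rbind, summaries)
  tab <- cbind(subject = names(summaries), tab)
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
  invisible(path)
}

#' Temporal signal-to-noise ratio map and mask
#'
#' Per voxel, the time-series mean divided by its sample standard deviation
#' (N - 1 denominator). Zero-variance voxels get TSNR 0 and are excluded
#' from the thresholded mask. With `group_maps`, the group-level mask
#' thresholds the across-subject mean TSNR map instead.
#'
#' @param vol A [volume4d()] with T >= 2.
#' @param mask A [brain_mask()].
#' @param threshold TSNR ratio threshold; mask keeps voxels with TSNR
#'   strictly greater (default 30).
#' @param group_maps Optional list of subject-level TSNR result objects; the
#'   mask then thresholds their voxelwise mean map.
#' @return A `tsnr_result`: `map` ([volume4d()], single frame), `mask`
#'   ([brain_mask()]), `threshold`, `level`.
#' @export
tsnr <- function(vol, mask, threshold = 30, group_maps = NULL) {
  if (is.null(group_maps)) {
    mat <- volume_to_matrix(vol, mask)
    if (nrow(mat$values) < 2L) stop("TSNR requires at least 2 frames")
    mu <- colMeans(mat$values)
    sdv <- apply(mat$values, 2, stats::sd)
    ratio <- ifelse(sdv > 0, mu / sdv, 0)
    level <- "subject"
  } else {
    maps <- lapply(group_maps, function(g) {
      volume_to_matrix(g$map, mask)$values[1, ]
    })
    ratio <- Reduce(`+`, maps) / length(maps)
    level <- "group"
  }
  idx <- which(mask$data)
  map <- matrix_to_volume(
    ts_matrix(matrix(ratio, nrow = 1), idx, tr = 1, dim(mask$data)),
    mask)
  keep <- ratio > threshold & ratio != 0
  md <- array(FALSE, dim(mask$data))
  md[idx[keep]] <- TRUE
  if (!any(md)) {
    warning("no voxels survive the TSNR threshold")
    out_mask <- NULL
  } else out_mask <- brain_mask(md, affine = mask$affine)
  structure(list(map = map, mask = out_mask, threshold = threshold,
                 level = level),
            class = "tsnr_result")
}
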