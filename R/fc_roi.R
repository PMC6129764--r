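# ROI construction, signal extraction and functional connectivity.
#
# Connectivity matrices store the diagonal as 0 (not 1) so that network
# thresholding downstream never creates self-loops.

#' Construct an ROI atlas
#'
#' @param labels 3D array of non-negative integers; 0 is background.
#' @param affine 4x4 voxel-to-world transform.
#' @param table Optional label table (`data.frame` with `index`, `label`,
#'   optional `x`, `y`, `z` mm columns); generated from the label values if
#'   missing.
#' @return An `roi_atlas` object.
#' @export
roi_atlas <- function(labels, affine = diag(4), table = NULL) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array")
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(table))
    table <- data.frame(index = ids, label = sprintf("roi%02d", ids),
                        stringsAsFactors = FALSE)
  if (!all(ids %in% table$index))
    stop("label table is missing indices present in the image")
  if (anyDuplicated(table$index)) stop("duplicate indices in label table")
  structure(list(labels = labels, affine = unname(as.matrix(affine)),
                 table = table),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas> %s, %d regions\n",
              paste(dim(x$labels), collapse = " x "),
              sum(x$table$index %in% x$labels)))
  invisible(x)
}

#' Read / write an atlas label table (CSV)
#'
#' Columns: `index,label[,x,y,z,color,module]`; UTF-8, one header row.
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_label_table <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname read_label_table
#' @param table The label table to write.
#' @export
write_label_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw sphere or cube ROIs from coordinates
#'
#' Builds an atlas by stamping spheres (voxel-center Euclidean distance <=
#' radius) or cubes (each |axis offset| <= half-width) around world-mm
#' coordinates on the grid of a reference volume. Voxels claimed by several
#' ROIs go to the nearer center; exact ties go to the lower index.
#'
#' @param table Label table with `index`, `label`, `x`, `y`, `z` (mm).
#' @param shape `"sphere"` or `"cube"`.
#' @param size Radius (sphere) or half-width (cube), mm.
#' @param reference A [volume4d()] supplying grid and affine.
#' @param inclusive_mask Optional [brain_mask()] intersected with the
#'   result.
#' @return An [roi_atlas()]; ROIs that received no voxels stay in the table
#'   with a warning.
#' @export
draw_rois <- function(table, shape = c("sphere", "cube"), size, reference,
                      inclusive_mask = NULL) {
  shape <- match.arg(shape)
  stopifnot(inherits(reference, "volume4d"))
  d3 <- dim(reference$data)[1:3]
  nvox <- prod(d3)
  world <- voxel_to_world(reference$affine, index_to_ijk(seq_len(nvox), d3))
  lab <- integer(nvox)
  best <- rep(Inf, nvox)
  for (r in seq_len(nrow(table))) {
    ctr <- as.numeric(table[r, c("x", "y", "z")])
    off <- sweep(world, 2, ctr)
    dist <- sqrt(rowSums(off^2))
    inside <- if (shape == "sphere") dist <= size + 1e-9
              else apply(abs(off) <= size + 1e-9, 1, all)
    if (size == 0) inside <- dist == min(dist)
    take <- inside & dist < best - 1e-12
    lab[take] <- table$index[r]
    best[take] <- dist[take]
  }
  if (!is.null(inclusive_mask)) lab[!as.vector(inclusive_mask$data)] <- 0L
  empty <- setdiff(table$index, unique(lab))
  if (length(empty) > 0L)
    warning("ROIs with no voxels: ", paste(empty, collapse = ", "))
  roi_atlas(array(lab, dim = d3), affine = reference$affine, table = table)
}

#' Merge binary masks into an atlas, or extract ROIs from one
#'
#' Merge mode labels the input masks 1..k in order and emits a label table;
#' overlapping masks are an error (no silent precedence). Extract mode
#' returns the union mask of the requested label ids.
#'
#' @param inputs For merge: list of [brain_mask()] on a common grid. For
#'   extract: an [roi_atlas()].
#' @param mode `"merge"` or `"extract"`.
#' @param ids Label ids to extract (extract mode).
#' @return An [roi_atlas()] (merge) or [brain_mask()] (extract).
#' @export
merge_extract <- function(inputs, mode = c("merge", "extract"), ids = NULL) {
  mode <- match.arg(mode)
  if (mode == "merge") {
    stopifnot(is.list(inputs), length(inputs) >= 1L)
    ref <- inputs[[1]]
    lab <- array(0L, dim(ref$data))
    for (k in seq_along(inputs)) {
      m <- inputs[[k]]
      check_grid(dim(ref$data), ref$affine, dim(m$data), m$affine, "masks")
      overlap <- sum(lab[m$data] != 0L)
      if (overlap > 0L)
        stop("mask ", k, " overlaps previously merged masks at ",
             overlap, " voxel(s)")
      lab[m$data] <- k
    }
    roi_atlas(lab, affine = ref$affine)
  } else {
    stopifnot(inherits(inputs, "roi_atlas"))
    present <- unique(inputs$labels[inputs$labels > 0L])
    missing <- setdiff(ids, present)
    if (length(missing) > 0L)
      stop("ids absent from atlas: ", paste(missing, collapse = ", "))
    brain_mask(inputs$labels %in% ids & inputs$labels > 0L,
               affine = inputs$affine)
  }
}

#' Mean time series per ROI
#'
#' Row r is the unweighted mean series over the in-mask member voxels of
#' ROI r. ROIs with no in-mask voxels yield an all-`NA` row with a warning.
#'
#' @param mat A `ts_matrix` extracted with `mask`.
#' @param atlas An [roi_atlas()] on the same grid.
#' @param mask The [brain_mask()] used for extraction.
#' @return ROI x frames matrix with rownames from the label table.
#' @export
roi_timeseries <- function(mat, atlas, mask) {
  stopifnot(inherits(mat, "ts_matrix"), inherits(atlas, "roi_atlas"))
  check_grid(dim(mask$data), mask$affine, dim(atlas$labels), atlas$affine,
             "mask and atlas")
  ids <- atlas$table$index
  lab_at_cols <- atlas$labels[mat$voxel_index]
  out <- matrix(NA_real_, length(ids), nrow(mat$values))
  rownames(out) <- atlas$table$label
  for (k in seq_along(ids)) {
    cols <- which(lab_at_cols == ids[k])
    if (length(cols) == 0L) {
      warning("ROI ", ids[k], " has no in-mask voxels; row set missing")
      next
    }
    out[k, ] <- rowMeans(mat$values[, cols, drop = FALSE])
  }
  out
}

#' Fisher z transform of correlations
#'
#' z = 0.5 log((1 + r) / (1 - r)); |r| = 1 is clipped to 1 - 1e-7 before
#' the transform (with a warning) so downstream t-tests see finite values.
#'
#' @param r Correlations, |r| <= 1 (vector or matrix).
#' @return z values, same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| > 1 is not a correlation")
  clip <- !is.na(r) & abs(r) >= 1 - .Machine$double.eps
  if (any(clip)) {
    warning("|r| = 1 clipped to 1 - 1e-7 before Fisher z")
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' ROI-to-ROI connectivity
#'
#' Pearson correlation between all ROI pairs, optionally partial: the
#' partial correlation of ROIs i and j conditions on the mean signals of
#' all other ROIs (plus an intercept). A Fisher-z companion matrix is
#' returned alongside. Diagonals are stored as 0.
#'
#' @param roi_ts ROI x frames matrix from [roi_timeseries()].
#' @param partial Compute partial instead of plain correlations.
#' @return A `connectivity_matrix`: `values` (N x N), `z` (Fisher-z
#'   companion), `node_labels`, `kind`.
#' @export
roi_connectivity <- function(roi_ts, partial = FALSE) {
  X <- t(as.matrix(roi_ts))   # frames x ROIs
  n <- ncol(X)
  nt <- nrow(X)
  if (nt < 3L) stop("connectivity requires at least 3 frames")
  labels <- colnames(X)
  if (is.null(labels)) labels <- sprintf("roi%02d", seq_len(n))
  dead <- apply(X, 2, stats::sd) == 0 | apply(is.na(X), 2, any)
  if (any(dead))
    warning("zero-variance or missing ROI series: ",
            paste(labels[dead], collapse = ", "), "; set missing")
  if (partial && nt <= n)
    stop("partial correlation requires more frames than ROIs")
  ok <- which(!dead)
  R <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  if (partial) {
    # partial correlation from the inverse covariance of the retained ROIs
    S <- stats::cov(X[, ok, drop = FALSE])
    P <- solve(S)
    pr <- -P / sqrt(diag(P) %o% diag(P))
    R[ok, ok] <- pr
  } else {
    R[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  }
  diag(R) <- 0
  Z <- fisher_z(R)
  connectivity_matrix(R, labels,
                      kind = if (partial) "partial" else "pearson", z = Z)
}

#' Construct a connectivity matrix
#'
#' @param values N x N symmetric matrix, diagonal 0 by convention.
#' @param node_labels N node names.
#' @param kind `"pearson"`, `"partial"` or `"fisher_z"`.
#' @param z Optional Fisher-z companion.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, node_labels = NULL,
                                kind = "pearson", z = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity must be square")
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-8)
    stop("connectivity matrix is not symmetric (max asymmetry ", asym, ")")
  if (is.null(node_labels))
    node_labels <- sprintf("node%02d", seq_len(nrow(values)))
  dimnames(values) <- list(node_labels, node_labels)
  structure(list(values = values, z = z, node_labels = node_labels,
                 kind = kind),
            class = "connectivity_matrix")
}

#' Read / write a connectivity matrix (CSV with header row = node labels)
#'
#' @param path CSV path.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  connectivity_matrix(as.matrix(tab), node_labels = colnames(tab))
}

#' @rdname read_connectivity
#' @param cm The connectivity matrix to write.
#' @export
write_connectivity <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$values), path, row.names = FALSE)
  invisible(path)
}

#' ROI centers of mass
#'
#' Per ROI, the unweighted mean of member voxel world coordinates (mm).
#'
#' @param atlas An [roi_atlas()].
#' @return The atlas label table with `x`, `y`, `z` columns filled in;
#'   empty ROIs get `NA` with a warning.
#' @export
roi_centers <- function(atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  d3 <- dim(atlas$labels)
  tab <- atlas$table
  tab$x <- tab$y <- tab$z <- NA_real_
  for (r in seq_len(nrow(tab))) {
    idx <- which(atlas$labels == tab$index[r])
    if (length(idx) == 0L) {
      warning("ROI ", tab$index[r], " is empty; no center computed")
      next
    }
    w <- voxel_to_world(atlas$affine, index_to_ijk(idx, d3))
    tab[r, c("x", "y", "z")] <- colMeans(w)
  }
  tab[, union(c("index", "label", "x", "y", "z"), names(tab))]
}

#' Extract per-subject signals into a table
#'
#' One row per subject. For 3D maps the selector is a [brain_mask()]
#' (columns = voxel values in linear order) or an [roi_atlas()] (columns =
#' per-ROI means). For square 2D matrices, `selector = "upper_triangle"`
#' flattens the strict upper triangle row-major (i < j).
#'
#' @param inputs List of single-frame [volume4d()] maps or square matrices.
#' @param selector A [brain_mask()], [roi_atlas()], or
#'   `"upper_triangle"`.
#' @return A `data.frame`, subjects x signals.
#' @export
extract_table <- function(inputs, selector) {
  rows <- lapply(seq_along(inputs), function(s) {
    x <- inputs[[s]]
    if (identical(selector, "upper_triangle")) {
      m <- if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
      if (nrow(m) != ncol(m)) stop("input ", s, " is not square")
      ut <- t(m)[lower.tri(t(m))]   # row-major i < j
      names(ut) <- ut_names(nrow(m), rownames(m))
      ut
    } else if (inherits(selector, "brain_mask")) {
      stopifnot(inherits(x, "volume4d"))
      check_grid(dim(x$data), x$affine, dim(selector$data),
                 selector$affine, paste("input", s, "and mask"))
      v <- as.vector(x$data[, , , 1])[which(selector$data)]
      names(v) <- paste0("v", which(selector$data))
      v
    } else if (inherits(selector, "roi_atlas")) {
      stopifnot(inherits(x, "volume4d"))
      check_grid(dim(x$data), x$affine, dim(selector$labels),
                 selector$affine, paste("input", s, "and atlas"))
      v <- vapply(selector$table$index, function(id)
        mean(x$data[, , , 1][selector$labels == id]), numeric(1))
      names(v) <- selector$table$label
      v
    } else stop("unsupported selector")
  })
  len <- vapply(rows, length, integer(1))
  if (length(unique(len)) != 1L)
    stop("inconsistent input shapes: input ",
         which(len != len[1])[1], " differs")
  as.data.frame(do.call(rbind, rows))
}

ut_names <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste0(labels[idx[, 1]], "_", labels[idx[, 2]])
}
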