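ref_volume <- function(dims = c(9, 9, 9))
  volume4d(array(0, c(dims, 1)), affine = diag(c(3, 3, 3, 1)))

test_that("sphere and cube ROIs contain exactly the enumerated voxels", {
  ref <- ref_volume()
  # center on the voxel-center at (12, 12, 12) mm = voxel (5,5,5)
  tab <- data.frame(index = 1, label = "a", x = 12, y = 12, z = 12)
  one <- draw_rois(tab, "sphere", 0, ref)
  expect_equal(which(one$labels == 1),
               5 + 4 * 9 + 4 * 81)
  sph <- draw_rois(tab, "sphere", 3, ref)
  expect_equal(sum(sph$labels == 1), 7)   # center + 6 face neighbors
  cub <- draw_rois(tab, "cube", 3, ref)
  expect_equal(sum(cub$labels == 1), 27)  # 3 voxels per axis
})

test_that("overlapping ROIs resolve to the nearer center, ties to lower id", {
  ref <- ref_volume()
  tab <- data.frame(index = 1:2, label = c("a", "b"),
                    x = c(9, 15), y = 12, z = 12)
  atl <- draw_rois(tab, "sphere", 4, ref)
  # the voxel at x = 12 mm is equidistant: goes to index 1
  mid <- 5 + 4 * 9 + 4 * 81
  expect_equal(atl$labels[mid], 1L)
  # voxels nearer each center belong to it
  expect_equal(atl$labels[4 + 4 * 9 + 4 * 81], 1L)
  expect_equal(atl$labels[6 + 4 * 9 + 4 * 81], 2L)
})

test_that("empty ROIs warn but stay in the table", {
  ref <- ref_volume()
  tab <- data.frame(index = 1:2, label = c("in", "out"),
                    x = c(12, 500), y = 12, z = 12)
  expect_warning(atl <- draw_rois(tab, "sphere", 3, ref), "no voxels")
  expect_equal(nrow(atl$table), 2L)
  expect_false(2 %in% atl$labels)
})

test_that("merge assigns labels in input order, rejects overlap", {
  d <- c(4, 4, 1)
  m1 <- array(FALSE, d); m1[1:2, 1, 1] <- TRUE
  m2 <- array(FALSE, d); m2[3:4, 4, 1] <- TRUE
  a1 <- brain_mask(m1); a2 <- brain_mask(m2)
  atl <- merge_extract(list(a1, a2), "merge")
  expect_equal(sum(atl$labels == 1), 2)
  expect_equal(sum(atl$labels == 2), 2)
  m3 <- array(FALSE, d); m3[2:3, 1, 1] <- TRUE   # overlaps m1 at 1 voxel
  expect_error(merge_extract(list(a1, brain_mask(m3)), "merge"),
               "1 voxel")
  # extraction
  ext <- merge_extract(atl, "extract", ids = 2)
  expect_equal(which(ext$data), which(m2))
  expect_error(merge_extract(atl, "extract", ids = 9), "absent")
})

test_that("ROI time series are unweighted member means", {
  dims <- c(4, 1, 1)
  nt <- 12
  vol <- random_volume(dims, nt = nt, seed = 80)
  mask <- full_mask(dims)
  lab <- array(c(1L, 2L, 2L, 0L), dims)
  atl <- roi_atlas(lab, affine = mask$affine)
  mat <- volume_to_matrix(vol, mask)
  rts <- roi_timeseries(mat, atl, mask)
  expect_equal(rts[1, ], vol$data[1, 1, 1, ], ignore_attr = TRUE)
  expect_equal(rts[2, ], (vol$data[2, 1, 1, ] + vol$data[3, 1, 1, ]) / 2,
               ignore_attr = TRUE)
  # ROI fully outside the mask: flagged missing
  mask2 <- brain_mask(array(c(TRUE, TRUE, TRUE, FALSE), dims),
                      affine = vol$affine)
  lab2 <- array(c(1L, 1L, 0L, 2L), dims)
  atl2 <- roi_atlas(lab2, affine = mask2$affine)
  mat2 <- volume_to_matrix(vol, mask2)
  expect_warning(rts2 <- roi_timeseries(mat2, atl2, mask2), "no in-mask")
  expect_true(all(is.na(rts2[2, ])))
})

test_that("fisher z: closed form, odd symmetry, clipping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(0.1, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_equal(z1, 0.5 * log((2 - 1e-7) / 1e-7))
  expect_error(fisher_z(1.2), "not a correlation")
})

test_that("connectivity is symmetric, zero-diagonal, correct on identical
           series", {
  set.seed(81)
  nt <- 30
  base <- rnorm(nt)
  rts <- rbind(a = base, b = base, c = rnorm(nt))
  expect_warning(cm <- roi_connectivity(rts), "clipped")
  expect_equal(cm$values["a", "b"], 1)
  expect_equal(cm$values, t(cm$values))
  expect_true(all(diag(cm$values) == 0))
  expect_equal(cm$z["a", "b"], fisher_z(1 - 1e-7) + 0, tolerance = 1e-9)
})

test_that("partial correlation equals the two-step residual oracle", {
  set.seed(82)
  nt <- 60
  r1 <- rnorm(nt)
  r2 <- 0.4 * r1 + rnorm(nt)
  r3 <- r1 + 0.6 * rnorm(nt)
  rts <- rbind(roi1 = r1, roi2 = r2, roi3 = r3)
  pc <- roi_connectivity(rts, partial = TRUE)
  # oracle: regress roi1 and roi2 each on [1, roi3], correlate residuals
  e1 <- stats::residuals(stats::lm(r1 ~ r3))
  e2 <- stats::residuals(stats::lm(r2 ~ r3))
  expect_equal(pc$values["roi1", "roi2"], stats::cor(e1, e2),
               tolerance = 1e-10)
  expect_error(roi_connectivity(rts[, 1:3], partial = TRUE),
               "more frames")
})

test_that("partial with an uninformative covariate equals plain Pearson", {
  set.seed(83)
  nt <- 50
  r1 <- rnorm(nt)
  r2 <- 0.5 * r1 + rnorm(nt)
  r3 <- rnorm(nt) * 1e-8 + rnorm(nt)   # independent of both
  pc <- roi_connectivity(rbind(a = r1, b = r2, c = r3), partial = TRUE)
  pl <- roi_connectivity(rbind(a = r1, b = r2, c = r3))
  # conditioning on an independent series changes r(a,b) only slightly
  expect_equal(pc$values["a", "b"], pl$values["a", "b"], tolerance = 0.05)
})

test_that("correlation is invariant under per-ROI affine rescaling", {
  set.seed(84)
  rts <- matrix(rnorm(4 * 40), 4, 40)
  rownames(rts) <- paste0("r", 1:4)
  c1 <- roi_connectivity(rts)
  c2 <- roi_connectivity(rts * c(2, 3, 0.5, 10) + c(1, -5, 0, 2))
  expect_equal(c1$values, c2$values, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("roi_centers: single voxel, midpoint, and brute-force blobs", {
  d <- c(5, 5, 2)
  lab <- array(0L, d)
  lab[2, 3, 1] <- 1L
  lab[1, 1, 1] <- 2L
  lab[5, 1, 1] <- 2L
  atl <- roi_atlas(lab, affine = diag(c(3, 3, 3, 1)))
  ctr <- roi_centers(atl)
  expect_equal(unlist(ctr[1, c("x", "y", "z")]),
               c(x = 3, y = 6, z = 0))
  expect_equal(unname(unlist(ctr[2, c("x", "y", "z")])), c(6, 0, 0))

  atl2 <- generate_atlas(c(6, 6, 3), 2, min_size = 5, seed = 85)
  ctr2 <- roi_centers(atl2)
  for (r in 1:2) {
    idx <- which(atl2$labels == r)
    w <- voxel_to_world(atl2$affine,
                        restbold:::index_to_ijk(idx, c(6, 6, 3)))
    expect_equal(unname(unlist(ctr2[r, c("x", "y", "z")])), colMeans(w))
  }
})

test_that("drawn sphere centers round-trip through roi_centers", {
  ref <- ref_volume()
  tab <- data.frame(index = 1:2, label = c("a", "b"),
                    x = c(6, 18), y = c(6, 18), z = c(12, 6))
  atl <- draw_rois(tab, "sphere", 3, ref)
  ctr <- roi_centers(atl)
  expect_equal(ctr$x, tab$x)
  expect_equal(ctr$y, tab$y)
  expect_equal(ctr$z, tab$z)
})

test_that("label tables and connectivity matrices round-trip through CSV", {
  tab <- data.frame(index = 1:3, label = c("a", "b", "c"),
                    x = c(0, 3, 6), y = 0, z = 0)
  f <- tempfile(fileext = ".csv")
  write_label_table(tab, f)
  expect_equal(read_label_table(f), tab)

  set.seed(86)
  cm <- roi_connectivity(matrix(rnorm(3 * 30), 3, 30,
                                dimnames = list(c("a", "b", "c"), NULL)))
  f2 <- tempfile(fileext = ".csv")
  write_connectivity(cm, f2)
  back <- read_connectivity(f2)
  expect_equal(back$values, cm$values, tolerance = 1e-12)
  expect_equal(back$node_labels, cm$node_labels)
})

test_that("extract_table flattens maps, ROI means and upper triangles", {
  dims <- c(3, 2, 1)
  mk_map <- function(seed) random_volume(dims, nt = 1, seed = seed)
  maps <- list(mk_map(1), mk_map(2), mk_map(3))
  lab <- array(c(1L, 1L, 0L, 2L, 2L, 2L), dims)
  atl <- roi_atlas(lab, affine = maps[[1]]$affine)
  tab <- extract_table(maps, atl)
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(tab[1, 1], mean(maps[[1]]$data[, , , 1][lab == 1]))

  # single voxel mask
  md <- array(FALSE, dims); md[2, 1, 1] <- TRUE
  t1 <- extract_table(maps[1], brain_mask(md, affine = maps[[1]]$affine))
  expect_equal(dim(t1), c(1L, 1L))
  expect_equal(t1[1, 1], maps[[1]]$data[2, 1, 1, 1])

  # upper triangle, row-major i < j
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  ut <- extract_table(list(m), "upper_triangle")
  expect_equal(unname(unlist(ut[1, ])), c(1, 2, 3))
  expect_equal(ncol(ut), 3L)   # N(N-1)/2
  expect_error(extract_table(list(m, matrix(0, 4, 4)), "upper_triangle"),
               "inconsistent")
})
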