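test_that("map normalization hits its exact targets", {
  vol <- random_volume(c(4, 4, 2), nt = 1, seed = 3)
  mask <- full_mask(c(4, 4, 2))
  z <- map_values(normalize_map(vol, mask, "zscore"), mask)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::sd(z) - 1), 1e-12)

  fives <- volume4d(array(5, c(4, 4, 2, 1)), affine = vol$affine)
  m <- map_values(normalize_map(fives, mask, "mean"), mask)
  expect_true(all(m == 1))
  expect_error(normalize_map(fives, mask, "zscore"), "sd is 0")
})

test_that("amplitude formulas evaluate exactly on hand cases", {
  m <- ts_matrix(cbind(c(1, -1, 1, -1), rep(3, 4)), 1:2, 2, c(2, 1, 1))
  am <- amplitude(m)
  expect_equal(am$am_mean[1], 1)
  expect_equal(am$am_std[1], sqrt(4 / 3))
  expect_equal(am$am_mean[2], 0)   # constant series
  expect_equal(am$am_std[2], 0)
  # homogeneity: scaling by c scales both by |c|
  m2 <- ts_matrix(m$values * -2.5, 1:2, 2, c(2, 1, 1))
  am2 <- amplitude(m2)
  expect_equal(am2$am_mean, 2.5 * am$am_mean)
  expect_equal(am2$am_std, 2.5 * am$am_std)
  expect_error(amplitude(ts_matrix(matrix(1, 1, 1), 1L, 2, c(1, 1, 1))),
               "2 frames")
})

test_that("ALFF scales linearly; fALFF of an in-band phantom is near 1", {
  tr <- 2
  nt <- 200
  t_sec <- (0:(nt - 1)) * tr
  x <- sin(2 * pi * 0.04 * t_sec) + 0.5 * sin(2 * pi * 0.07 * t_sec)
  m <- ts_matrix(cbind(x, 2 * x), 1:2, tr, c(2, 1, 1))
  r <- alff_falff(m, c(0.01, 0.08))
  expect_equal(r$alff[2], 2 * r$alff[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(r$falff[1], 0.98)   # all planted power is in band

  # zero-signal voxel gets fALFF 0
  z <- alff_falff(ts_matrix(matrix(0, nt, 1), 1L, tr, c(1, 1, 1)),
                  c(0.01, 0.08))
  expect_equal(z$falff[1], 0)
  expect_error(alff_falff(ts_matrix(matrix(rnorm(10), 10, 1), 1L, 0.5,
                                    c(1, 1, 1)),
                          c(0.011, 0.012)),
               "bins")
})

test_that("white-noise fALFF concentrates on the band's bin fraction", {
  set.seed(41)
  tr <- 2
  nt <- 100
  nv <- 1000
  m <- ts_matrix(matrix(rnorm(nt * nv), nt, nv), 1:nv, tr, c(nv, 1, 1))
  band <- c(0.01, 0.08)
  r <- alff_falff(m, band)
  f <- (1:(nt / 2)) / (nt * tr)
  q <- mean(f >= band[1] & f <= band[2])
  expect_lt(abs(mean(r$falff) - q), 3 * stats::sd(r$falff) / sqrt(nv) + 0.01)
})

test_that("ALFF and fALFF are invariant to time reversal", {
  set.seed(42)
  nt <- 80
  m <- ts_matrix(matrix(rnorm(nt * 5), nt, 5), 1:5, 2, c(5, 1, 1))
  rev_m <- ts_matrix(m$values[nt:1, ], 1:5, 2, c(5, 1, 1))
  a <- alff_falff(m, c(0.01, 0.08))
  b <- alff_falff(rev_m, c(0.01, 0.08))
  expect_equal(a$alff, b$alff, tolerance = 1e-10)
  expect_equal(a$falff, b$falff, tolerance = 1e-10)
})

test_that("ReHo equals the brute-force Kendall's W oracle", {
  # hand case: K = 3 series over n = 3 frames with a known rank matrix
  ranks <- cbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3))
  series <- apply(ranks, 2, function(r) as.numeric(r))
  expect_equal(oracle_kendall_w(series),
               (sum(rowSums(ranks)^2) - 3 * mean(rowSums(ranks))^2) /
                 ((1 / 12) * 9 * (27 - 3)))

  # random (K, n) instances: the package's rank-sum kernel vs the
  # definitional oracle
  set.seed(50)
  for (rep in 1:200) {
    K <- sample(c(2, 3, 5, 7, 19, 27), 1)
    n <- sample(5:40, 1)
    S <- matrix(rnorm(n * K), n, K)
    w_pkg <- restbold:::kendall_w_from_ranks(apply(S, 2, rank))
    expect_equal(w_pkg, oracle_kendall_w(S), tolerance = 1e-12)
  }
})

test_that("ReHo map: identical series give W = 1; neighborhoods shrink at
           the boundary", {
  dims <- c(3, 3, 3)
  nt <- 30
  sig <- sin(seq_len(nt))
  vol <- volume4d(array(rep(sig, each = 27), c(dims, nt)),
                  affine = diag(c(3, 3, 3, 1)), tr = 2)
  mask <- full_mask(dims)
  w <- map_values(reho(volume_to_matrix(vol, mask), mask,
                       neighbor_scheme("vertex")), mask)
  expect_equal(w, rep(1, 27), tolerance = 1e-12)

  # random data: every voxel's W matches the oracle on its own (shrunken)
  # neighborhood
  vol2 <- random_volume(dims, nt = 20, seed = 51)
  mat <- volume_to_matrix(vol2, mask)
  w2 <- map_values(reho(mat, mask, neighbor_scheme("face")), mask)
  sch <- neighbor_scheme("face")
  for (v in c(1, 5, 14, 27)) {   # corner, edge, center, corner
    ijk <- arrayInd(v, dims)
    nbs <- v
    for (o in seq_len(nrow(sch$offsets))) {
      n <- ijk + sch$offsets[o, ]
      if (any(n < 1) || any(n > dims)) next
      nbs <- c(nbs, n[1] + (n[2] - 1) * 3 + (n[3] - 1) * 9)
    }
    expect_equal(w2[v], oracle_kendall_w(mat$values[, nbs]),
                 tolerance = 1e-12, label = paste("voxel", v))
  }
})

test_that("W is in [0,1] and invariant under monotone transforms", {
  vol <- random_volume(c(4, 4, 2), nt = 25, seed = 52)
  mask <- full_mask(c(4, 4, 2))
  mat <- volume_to_matrix(vol, mask)
  w1 <- map_values(reho(mat, mask), mask)
  expect_true(all(w1 >= 0 & w1 <= 1))
  mono <- ts_matrix(exp(mat$values / 2), mat$voxel_index, mat$tr,
                    mat$source_shape)
  w2 <- map_values(reho(mono, mask), mask)
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("mean W of independent series agrees with a permutation oracle", {
  set.seed(53)
  n <- 200
  K <- 27
  reps <- 120
  w_impl <- replicate(reps,
    restbold:::kendall_w_from_ranks(apply(matrix(rnorm(n * K), n, K), 2,
                                          rank)))
  # oracle: W computed definitionally on independently permuted ranks
  w_orac <- replicate(reps, {
    R <- replicate(K, sample.int(n))
    oracle_kendall_w(R)
  })
  se <- sqrt(stats::var(w_impl) / reps + stats::var(w_orac) / reps)
  expect_lt(abs(mean(w_impl) - mean(w_orac)), 4 * se)
})

test_that("FCD recovers planted blob structure", {
  dims <- c(6, 6, 2)
  lin <- function(i, j, k) i + (j - 1) * 6 + (k - 1) * 36
  # one contiguous 10-voxel blob
  blob <- c(lin(2, 2, 1), lin(3, 2, 1), lin(2, 3, 1), lin(3, 3, 1),
            lin(2, 2, 2), lin(3, 2, 2), lin(2, 3, 2), lin(3, 3, 2),
            lin(4, 2, 1), lin(4, 3, 1))
  fx <- blob_volume(dims, blob, nt = 120, seed = 61)
  mat <- volume_to_matrix(fx$vol, fx$mask)
  r <- fcd(mat, fx$mask, r_threshold = 0.6)
  seed_col <- which(mat$voxel_index == blob[1])
  expect_equal(map_values(r$gfcd, fx$mask)[seed_col], 9)
  expect_equal(map_values(r$lfcd, fx$mask)[seed_col], 9)
  expect_equal(map_values(r$lrfcd, fx$mask)[seed_col], 0)

  # two disconnected blobs (5 + 4) sharing one signal; seed in the 5-blob
  blob5 <- c(lin(1, 1, 1), lin(2, 1, 1), lin(1, 2, 1), lin(2, 2, 1),
             lin(1, 1, 2))
  blob4 <- c(lin(5, 5, 2), lin(6, 5, 2), lin(5, 6, 2), lin(6, 6, 2))
  fx2 <- blob_volume(dims, c(blob5, blob4), nt = 150, seed = 62,
                     noise = 0.05)
  mat2 <- volume_to_matrix(fx2$vol, fx2$mask)
  r2 <- fcd(mat2, fx2$mask, r_threshold = 0.6)
  s <- which(mat2$voxel_index == blob5[1])
  expect_equal(map_values(r2$gfcd, fx2$mask)[s], 8)
  expect_equal(map_values(r2$lfcd, fx2$mask)[s], 4)
  expect_equal(map_values(r2$lrfcd, fx2$mask)[s], 4)

  # independent noise at an extreme threshold: all zero
  vol3 <- random_volume(c(4, 4, 1), nt = 100, seed = 63)
  mask3 <- full_mask(c(4, 4, 1))
  r3 <- fcd(volume_to_matrix(vol3, mask3), mask3, r_threshold = 0.99)
  expect_true(all(map_values(r3$gfcd, mask3) == 0))
  expect_true(all(map_values(r3$lfcd, mask3) == 0))
})

test_that("gFCD = lFCD + lrFCD and metrics ignore per-voxel rescaling", {
  vol <- random_volume(c(4, 4, 2), nt = 60, seed = 64)
  mask <- full_mask(c(4, 4, 2))
  mat <- volume_to_matrix(vol, mask)
  r <- fcd(mat, mask, r_threshold = 0.3)
  expect_equal(map_values(r$gfcd, mask),
               map_values(r$lfcd, mask) + map_values(r$lrfcd, mask))
  scaled <- ts_matrix(sweep(mat$values, 2, runif(32, 0.5, 3), `*`),
                      mat$voxel_index, mat$tr, mat$source_shape)
  r2 <- fcd(scaled, mask, r_threshold = 0.3)
  expect_equal(map_values(r$gfcd, mask), map_values(r2$gfcd, mask))
  expect_equal(map_values(r$lfcd, mask), map_values(r2$lfcd, mask))
})

test_that("bit-packed FCD equals the dense float path on random fixtures", {
  for (s in 1:50) {
    set.seed(1000 + s)
    dims <- c(10, 10, 2)   # 200 voxels
    nt <- 30
    vol <- volume4d(array(rnorm(prod(dims) * nt), c(dims, nt)),
                    affine = diag(c(3, 3, 3, 1)), tr = 2)
    mask <- full_mask(dims)
    mat <- volume_to_matrix(vol, mask)
    thr <- runif(1, 0.2, 0.6)
    a <- fcd(mat, mask, r_threshold = thr, packed = TRUE)
    b <- fcd(mat, mask, r_threshold = thr, packed = FALSE)
    expect_identical(lapply(a, function(v) v$data),
                     lapply(b, function(v) v$data))
  }
})

test_that("packed adjacency uses 1/32 the bytes of a dense float32 store", {
  set.seed(70)
  nv <- 1000
  cmat <- stats::cor(matrix(rnorm(40 * nv), 40, nv))
  adj <- pack_adjacency(cmat, 0.3)
  expect_equal(adj$bytes * 32, adj$float_bytes)
})

test_that("FCS matches a brute-force evaluation of its definition", {
  set.seed(71)
  nt <- 50
  Y <- matrix(rnorm(nt * 4), nt, 4)
  Y[, 2] <- Y[, 1] + 0.3 * rnorm(nt)   # strong pair
  m <- ts_matrix(Y, 1:4, 2, c(4, 1, 1))
  thr <- 0.25
  got <- fcs(m, threshold = thr)
  want <- numeric(4)
  for (i in 1:4) {
    acc <- 0
    for (j in 1:4) {
      if (i == j) next
      z <- atanh(stats::cor(Y[, i], Y[, j]))
      if (z > thr) acc <- acc + z
    }
    want[i] <- acc / 3
  }
  expect_equal(got, want, tolerance = 1e-12)

  # threshold above every |z| -> all zero
  expect_true(all(fcs(m, threshold = 10) == 0))

  # adding an uncorrelated voxel rescales by (V-1)/V
  set.seed(72)
  Y5 <- cbind(Y, rnorm(nt) * 1e-2 + rnorm(nt))
  m5 <- ts_matrix(Y5, 1:5, 2, c(5, 1, 1))
  got5 <- fcs(m5, threshold = thr)
  # only exact if the new voxel adds no supra-threshold edges
  z_new <- atanh(abs(stats::cor(Y5[, 5], Y)))
  if (all(z_new <= thr))
    expect_equal(got5[1:4], got * 3 / 4, tolerance = 1e-12)
})
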