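# Shared fixtures and independent brute-force oracles. Oracles here are
# written from the definitions (loops, enumeration) and never reuse the
# package's vectorized code paths.

random_volume <- function(dims = c(4, 4, 4), nt = 10, seed = 1, tr = 2) {
  set.seed(seed)
  volume4d(array(rnorm(prod(dims) * nt), c(dims, nt)),
           affine = diag(c(3, 3, 3, 1)), tr = tr)
}

full_mask <- function(dims = c(4, 4, 4))
  brain_mask(array(TRUE, dims), affine = diag(c(3, 3, 3, 1)))

# Volume with a contiguous blob sharing one signal plus small independent
# noise, all other voxels independent noise. Returns volume, mask and the
# blob's linear indices.
blob_volume <- function(dims = c(6, 6, 2), blob_idx, nt = 120, seed = 1,
                        noise = 0.1) {
  set.seed(seed)
  sig <- rnorm(nt)
  flat <- matrix(rnorm(prod(dims) * nt), prod(dims), nt)
  flat[blob_idx, ] <- matrix(rep(sig, each = length(blob_idx)),
                             length(blob_idx)) +
    noise * flat[blob_idx, , drop = FALSE]
  list(vol = volume4d(array(flat, c(dims, nt)),
                      affine = diag(c(3, 3, 3, 1)), tr = 2),
       mask = full_mask(dims), blob = blob_idx)
}

map_values <- function(map, mask) volume_to_matrix(map, mask)$values[1, ]

# --- oracles ---------------------------------------------------------------

# Kendall's W from the definition: explicit per-frame rank sums.
oracle_kendall_w <- function(series_matrix) {
  n <- nrow(series_matrix)
  K <- ncol(series_matrix)
  R <- matrix(0, n, K)
  for (j in seq_len(K)) R[, j] <- rank(series_matrix[, j])
  Ri <- numeric(n)
  for (i in seq_len(n)) Ri[i] <- sum(R[i, ])
  Rbar <- mean(Ri)
  num <- sum(Ri^2) - n * Rbar^2
  den <- (1 / 12) * K^2 * (n^3 - n)
  num / den
}

# All-pairs shortest paths by Floyd-Warshall on inverse-weight distances.
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && A[i, j] > 0) D[i, j] <- 1 / A[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(A) {
  D <- oracle_floyd_warshall(A)
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  tot / (n * (n - 1))
}

oracle_char_path_length <- function(A) {
  D <- oracle_floyd_warshall(A)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  mean(v)
}

# Binary clustering coefficient per node by triangle counting.
oracle_clustering <- function(A) {
  A <- (A > 0) + 0
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) { out[i] <- 0; next }
    links <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] > 0) links <- links + 1
    out[i] <- 2 * links / (k * (k - 1))
  }
  out
}

oracle_transitivity <- function(A) {
  A <- (A > 0) + 0
  n <- nrow(A)
  tri <- 0
  paths <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (A[i, j] && A[j, k]) {
      paths <- paths + 1
      if (A[i, k]) tri <- tri + 1
    }
  }
  if (paths == 0) 0 else tri / paths
}

# Betweenness by explicit enumeration of all shortest paths (binary graphs,
# small n), normalized by (N-1)(N-2)/2.
oracle_betweenness <- function(A) {
  A <- (A > 0) + 0
  n <- nrow(A)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    # BFS distances, then recursive enumeration of geodesics
    D <- oracle_floyd_warshall(A)
    if (!is.finite(D[s, t])) return(list())
    extend <- function(path) {
      v <- path[length(path)]
      if (v == t) return(list(path))
      nxt <- which(A[v, ] > 0 & D[, t] == D[v, t] - 1)
      unlist(lapply(nxt, function(u) extend(c(path, u))), recursive = FALSE)
    }
    extend(s)
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    for (pth in paths) {
      inner <- setdiff(pth, c(s, t))
      for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

random_graph_adjacency <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- ut[runif(length(ut)) < p_edge]
  A[on] <- 1
  A <- A + t(A)
  A
}

# Random symmetric weighted matrix in [0, 1), zero diagonal.
random_weight_matrix <- function(n, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  W + t(W)
}

make_network <- function(A, binarized = TRUE) {
  structure(list(adjacency = A,
                 threshold_meta = list(method = "intensity", value = 0,
                                       binarized = binarized),
                 node_labels = sprintf("n%02d", seq_len(nrow(A)))),
            class = "network")
}
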