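# Graph construction from connectivity matrices and complex-network metrics.
#
# Conventions (stated once, used everywhere):
#  - weighted path length uses 1/weight as the edge distance;
#  - characteristic path length excludes disconnected (infinite) pairs;
#    global efficiency counts them as 0;
#  - betweenness is normalized by (N-1)(N-2)/2;
#  - vulnerability = max_i (E - E_{-i})/E and fault tolerance =
#    mean_i E_{-i}/E, with E the global efficiency;
#  - the resilience proxy is the area under the largest-component-fraction
#    curve over targeted removal of the currently highest-degree node
#    (ties to the lowest index).

#' Threshold a connectivity matrix into a network
#'
#' Intensity mode keeps edges with weight strictly greater than `value`;
#' sparsity mode keeps the top `floor(s * N(N-1)/2)` edges by weight, ties
#' broken by (i, j) lexicographic order.
#'
#' @param cm A [connectivity_matrix()] (or plain symmetric matrix).
#' @param method `"intensity"` or `"sparsity"`.
#' @param value Intensity threshold, or sparsity in (0, 1].
#' @param binarize Map kept weights to 1.
#' @param negatives `"discard"` (drop negative weights before thresholding)
#'   or `"absolute"` (use absolute values).
#' @return A `network`: `adjacency`, `threshold_meta`, `node_labels`.
#' @export
threshold_network <- function(cm, method = c("sparsity", "intensity"),
                              value, binarize = TRUE,
                              negatives = c("discard", "absolute")) {
  method <- match.arg(method)
  negatives <- match.arg(negatives)
  W <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  labels <- if (inherits(cm, "connectivity_matrix")) cm$node_labels
            else sprintf("node%02d", seq_len(nrow(W)))
  if (max(abs(W - t(W)), na.rm = TRUE) > 1e-8)
    stop("connectivity matrix must be symmetric")
  diag(W) <- 0
  W[is.na(W)] <- 0
  W <- if (negatives == "absolute") abs(W) else pmax(W, 0)
  n <- nrow(W)
  A <- matrix(0, n, n)
  if (method == "intensity") {
    keep <- W > value
    A[keep] <- W[keep]
    if (sum(keep) == 0L) warning("intensity threshold leaves no edges")
  } else {
    if (value <= 0 || value > 1) stop("sparsity must be in (0, 1]")
    ut <- which(upper.tri(W), arr.ind = TRUE)
    ord <- order(-W[ut], ut[, 1], ut[, 2])
    k <- floor(value * n * (n - 1) / 2)
    if (k < 1L) stop("sparsity ", value, " keeps no edges for N = ", n)
    sel <- ut[ord[seq_len(k)], , drop = FALSE]
    A[sel] <- W[sel]
    A[sel[, 2:1, drop = FALSE]] <- W[sel]
  }
  if (binarize) A <- (A > 0) + 0
  structure(list(adjacency = A,
                 threshold_meta = list(method = method, value = value,
                                       binarized = binarize),
                 node_labels = labels),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network> %d nodes, %d edges (%s %g, %s)\n",
              nrow(x$adjacency), sum(x$adjacency > 0) / 2,
              x$threshold_meta$method, x$threshold_meta$value,
              if (x$threshold_meta$binarized) "binary" else "weighted"))
  invisible(x)
}

net_to_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      weighted = if (net$threshold_meta$binarized) NULL else TRUE,
                                      diag = FALSE)
}

# All-pairs shortest-path distances with 1/weight edge lengths (binary
# graphs: unit lengths).
net_distances <- function(net) {
  A <- net$adjacency
  D <- A
  D[A > 0] <- 1 / A[A > 0]
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = igraph::E(g)$weight)
}

global_efficiency_from_d <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

char_path_length_from_d <- function(D) {
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

# Efficiency of the subgraph induced by the neighbors of node i.
local_efficiency_node <- function(net, i) {
  nb <- which(net$adjacency[i, ] > 0)
  if (length(nb) < 2) return(0)
  sub <- structure(list(adjacency = net$adjacency[nb, nb, drop = FALSE],
                        threshold_meta = net$threshold_meta),
                   class = "network")
  global_efficiency_from_d(net_distances(sub))
}

drop_node <- function(net, i) {
  keep <- setdiff(seq_len(nrow(net$adjacency)), i)
  structure(list(adjacency = net$adjacency[keep, keep, drop = FALSE],
                 threshold_meta = net$threshold_meta,
                 node_labels = net$node_labels[keep]),
            class = "network")
}

# Area under the largest-component fraction curve over targeted removal of
# the currently highest-degree node; ties go to the lowest node index.
resilience_auc <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  fracs <- numeric(n)
  for (step in seq_len(n)) {
    if (nrow(A) == 0) { fracs[step] <- 0; next }
    g <- igraph::graph_from_adjacency_matrix((A > 0) + 0,
                                             mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)
    fracs[step] <- max(comp$csize) / n
    deg <- rowSums(A > 0)
    victim <- which.max(deg)   # which.max takes the first (lowest index) tie
    A <- A[-victim, -victim, drop = FALSE]
  }
  mean(fracs)
}

#' Global and nodal complex-network metrics
#'
#' Computes the standard undirected metrics on a thresholded network; see
#' the conventions in the package vignette (weighted distances are inverse
#' weights; disconnected pairs are excluded from the characteristic path
#' length and contribute zero efficiency).
#'
#' @param net A [threshold_network()] result.
#' @return A `network_metrics` list with `global` (characteristic path
#'   length, global efficiency, mean clustering, mean local efficiency,
#'   transitivity, assortativity, fault tolerance, vulnerability,
#'   resilience) and `nodal` (degree, strength, neighbor degree,
#'   clustering, betweenness, local efficiency).
#' @export
compute_metrics <- function(net) {
  stopifnot(inherits(net, "network"))
  A <- net$adjacency
  n <- nrow(A)
  if (n < 3) stop("network metrics require at least 3 nodes")
  if (sum(A > 0) == 0) stop("empty graph: no edges survive the threshold")
  D <- net_distances(net)
  E_glob <- global_efficiency_from_d(D)
  g_bin <- igraph::graph_from_adjacency_matrix((A > 0) + 0,
                                               mode = "undirected",
                                               diag = FALSE)
  clustering <- igraph::transitivity(g_bin, type = "localundirected",
                                     isolates = "zero")
  transitivity <- igraph::transitivity(g_bin, type = "global")
  if (is.nan(transitivity)) transitivity <- 0
  deg <- rowSums(A > 0)
  strength <- rowSums(A)
  nbdeg <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) == 0) 0 else mean(deg[nb])
  }, numeric(1))
  Dw <- D
  Dw[!is.finite(Dw)] <- 0
  gw <- if (net$threshold_meta$binarized) g_bin else {
    Ad <- A; Ad[A > 0] <- 1 / A[A > 0]
    igraph::graph_from_adjacency_matrix(Ad, mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
  }
  btw_raw <- igraph::betweenness(gw, directed = FALSE,
                                 weights = if (net$threshold_meta$binarized)
                                   NULL else igraph::E(gw)$weight)
  btw <- btw_raw / ((n - 1) * (n - 2) / 2)
  leff <- vapply(seq_len(n), function(i) local_efficiency_node(net, i),
                 numeric(1))
  E_minus <- vapply(seq_len(n), function(i)
    global_efficiency_from_d(net_distances(drop_node(net, i))), numeric(1))
  assort <- suppressWarnings(igraph::assortativity_degree(g_bin))
  structure(list(
    global = list(
      char_path_length = char_path_length_from_d(D),
      global_efficiency = E_glob,
      mean_clustering = mean(clustering),
      mean_local_efficiency = mean(leff),
      transitivity = transitivity,
      assortativity = assort,
      fault_tolerance = mean(E_minus) / E_glob,
      vulnerability = max((E_glob - E_minus) / E_glob),
      resilience = resilience_auc(net)),
    nodal = data.frame(
      node = net$node_labels, degree = deg, strength = strength,
      neighbor_degree = nbdeg, clustering = clustering,
      betweenness = btw, local_efficiency = leff)),
    class = "network_metrics")
}

#' Degree-preserving rewired null network
#'
#' Double-edge swaps preserving the degree sequence; seeded and
#' reproducible. Weighted networks are rewired on their binary structure
#' (null models are used for binary small-world calibration).
#'
#' @param net A [threshold_network()] result with at least 2 edges.
#' @param swaps_per_edge Swap attempts per edge (default 10).
#' @param seed Integer seed.
#' @return A rewired `network` with the same degree sequence.
#' @export
rewire_null <- function(net, swaps_per_edge = 10, seed = 1) {
  stopifnot(inherits(net, "network"))
  A <- (net$adjacency > 0) + 0
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < 2) stop("graph too small to rewire")
  with_seed(seed, {
    for (it in seq_len(swaps_per_edge * m)) {
      pick <- sample.int(m, 2)
      a <- edges[pick[1], ]
      b <- edges[pick[2], ]
      u <- a[1]; v <- a[2]; x <- b[1]; y <- b[2]
      if (length(unique(c(u, v, x, y))) < 4) next
      # propose (u,y) and (x,v)
      if (A[u, y] | A[x, v]) next
      A[u, v] <- A[v, u] <- 0
      A[x, y] <- A[y, x] <- 0
      A[u, y] <- A[y, u] <- 1
      A[x, v] <- A[v, x] <- 1
      edges[pick[1], ] <- sort(c(u, y))
      edges[pick[2], ] <- sort(c(x, v))
    }
  })
  structure(list(adjacency = A,
                 threshold_meta = list(method = net$threshold_meta$method,
                                       value = net$threshold_meta$value,
                                       binarized = TRUE),
                 node_labels = net$node_labels),
            class = "network")
}

#' Small-worldness against degree-preserving nulls
#'
#' sigma = (C / <C_null>) / (L / <L_null>) over `n_null` rewired null
#' networks, where C is the mean clustering coefficient and L the
#' characteristic path length (binary structure).
#'
#' @param net A connected [threshold_network()] result.
#' @param n_null Number of null networks (default 100).
#' @param seed Integer seed.
#' @param swaps_per_edge Swaps per edge for each null.
#' @return List: `sigma`, `c_ratio`, `l_ratio`, `c`, `l`, `c_null`,
#'   `l_null`.
#' @export
small_worldness <- function(net, n_null = 100, seed = 1,
                            swaps_per_edge = 10) {
  g <- igraph::graph_from_adjacency_matrix((net$adjacency > 0) + 0,
                                           mode = "undirected", diag = FALSE)
  if (igraph::components(g)$no > 1)
    stop("network is disconnected; raise the density before computing ",
         "small-worldness")
  cl_of <- function(A) {
    gg <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                              diag = FALSE)
    list(c = mean(igraph::transitivity(gg, type = "localundirected",
                                       isolates = "zero")),
         l = igraph::mean_distance(gg))
  }
  obs <- cl_of((net$adjacency > 0) + 0)
  nulls <- lapply(seq_len(n_null), function(i) {
    cl_of(rewire_null(net, swaps_per_edge, seed = seed + i)$adjacency)
  })
  c_null <- mean(vapply(nulls, `[[`, numeric(1), "c"))
  l_null <- mean(vapply(nulls, `[[`, numeric(1), "l"))
  c_ratio <- obs$c / c_null
  l_ratio <- obs$l / l_null
  list(sigma = c_ratio / l_ratio, c_ratio = c_ratio, l_ratio = l_ratio,
       c = obs$c, l = obs$l, c_null = c_null, l_null = l_null)
}

#' Compare network metrics between groups across thresholds
#'
#' Two-sample Student's t-tests (pooled variance) per metric per threshold.
#'
#' @param metrics Long-format `data.frame` with columns `subject`,
#'   `threshold`, `metric`, `value`.
#' @param groups Named vector or factor: group label per subject.
#' @return `data.frame` with one row per (metric, threshold): `t`, `df`,
#'   `p`.
#' @export
metrics_group_compare <- function(metrics, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  split_lab <- levels(groups)
  out <- list()
  for (m in unique(metrics$metric)) for (th in unique(metrics$threshold)) {
    sub <- metrics[metrics$metric == m & metrics$threshold == th, ]
    g <- groups[sub$subject]
    x <- sub$value[g == split_lab[1]]
    y <- sub$value[g == split_lab[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("each group needs at least 2 subjects for metric ", m)
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      # identical within groups: no evidence either way
      out[[length(out) + 1L]] <- data.frame(
        metric = m, threshold = th, t = 0,
        df = length(x) + length(y) - 2, p = 1)
      next
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      metric = m, threshold = th, t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value)
  }
  do.call(rbind, out)
}
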