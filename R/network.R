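#' Proportional sparsity thresholding
#'
#' Keeps the `k = round(sparsity * n(n-1)/2)` strongest connections of a
#' symmetric connectivity matrix (weights retained, not binarised) and
#' zeros the rest. Rounding is half-away-from-zero; ties at the weight
#' cutoff are resolved in favour of the smaller canonical edge index, so
#' the result is deterministic.
#'
#' @param mat symmetric nonnegative connectivity matrix.
#' @param sparsity fraction of edges to retain, in `(0, 1]`.
#' @return An object of class `weighted_network`: the thresholded weight
#'   matrix with attribute `sparsity`.
#' @export
proportional_threshold <- function(mat, sparsity) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("mat must be a square matrix")
  if (max(abs(mat - t(mat))) > 1e-8) stop("mat must be symmetric")
  if (sparsity <= 0 || sparsity > 1)
    stop("sparsity must lie in (0, 1]")
  n <- nrow(mat)
  pairs <- edge_pairs(n)
  w <- mat[pairs]
  k <- floor(sparsity * nrow(pairs) + 0.5)
  keep <- order(-w, seq_along(w))[seq_len(k)]
  out <- matrix(0, n, n, dimnames = dimnames(mat))
  kp <- pairs[keep, , drop = FALSE]
  out[kp] <- w[keep]
  out[kp[, 2:1, drop = FALSE]] <- w[keep]
  structure(out, sparsity = sparsity, class = c("weighted_network", "matrix"))
}

as_weight_matrix <- function(net) {
  m <- unclass(net)
  attr(m, "sparsity") <- NULL
  diag(m) <- 0
  m
}

igraph_from_weights <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted shortest path lengths
#'
#' Path length between two nodes is the minimum over connecting paths of
#' the sum of reciprocal edge weights (strong connections are short).
#' Computed by Dijkstra's algorithm; disconnected pairs get `Inf`.
#'
#' @param net a `weighted_network` or plain symmetric nonnegative matrix.
#' @return Square matrix of path lengths, zero diagonal.
#' @export
weighted_shortest_paths <- function(net) {
  w <- as_weight_matrix(net)
  g <- igraph_from_weights(w)
  if (igraph::ecount(g) == 0L) {
    d <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

#' Weighted characteristic path length
#'
#' Mean weighted shortest path length over all ordered node pairs. If the
#' thresholded graph is disconnected the mean diverges, so the value is
#' computed over the largest connected component and the attribute
#' `disconnected` is set to `TRUE`.
#'
#' @param net a `weighted_network` or symmetric matrix.
#' @return Scalar with logical attribute `disconnected`.
#' @export
characteristic_path_length <- function(net) {
  w <- as_weight_matrix(net)
  d <- weighted_shortest_paths(w)
  disconnected <- any(!is.finite(d))
  if (disconnected) {
    comp <- igraph::components(igraph_from_weights(w))
    keep <- which(comp$membership == which.max(comp$csize))
    d <- d[keep, keep, drop = FALSE]
  }
  n <- nrow(d)
  val <- if (n < 2L) Inf else sum(d[row(d) != col(d)]) / (n * (n - 1L))
  structure(val, disconnected = disconnected)
}

#' Weighted clustering coefficient
#'
#' Per node, the geometric-mean triangle intensity
#' `t_i = 1/2 * sum_{j,h} (w_ij w_ih w_jh)^(1/3)` normalised by the number
#' of neighbour pairs `k_i (k_i - 1) / 2`; the network value is the mean of
#' `2 t_i / (k_i (k_i - 1))` over all nodes, with nodes of degree < 2
#' contributing 0.
#'
#' @param net a `weighted_network` or symmetric matrix with weights in
#'   `[0, 1]`.
#' @return Scalar clustering coefficient.
#' @export
weighted_clustering <- function(net) {
  w <- as_weight_matrix(net)
  n <- nrow(w)
  wr <- w^(1 / 3)
  t_i <- diag(wr %*% wr %*% wr) / 2
  k_i <- rowSums(w > 0)
  c_i <- ifelse(k_i >= 2, 2 * t_i / (k_i * (k_i - 1)), 0)
  mean(c_i)
}

#' Weighted global efficiency
#'
#' Mean inverse weighted shortest path length over all ordered pairs, with
#' `1/Inf = 0` for disconnected pairs, so disconnection degrades rather
#' than breaks the metric.
#'
#' @param net a `weighted_network` or symmetric matrix.
#' @return Scalar in `[0, Inf)`; equals 1 for a complete unit-weight graph.
#' @export
global_efficiency <- function(net) {
  d <- weighted_shortest_paths(net)
  n <- nrow(d)
  if (n < 2L) return(0)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1L))
}

#' Weighted local efficiency
#'
#' For each node i with degree >= 2, the efficiency of its neighbourhood:
#' `E_loc(i) = 1/(k_i (k_i - 1)) * sum_{j != h in N_i}
#' (w_ij w_ih / l_jh(N_i))^(1/3)`, where `l_jh(N_i)` is the weighted
#' shortest path between neighbours j and h within the subgraph induced by
#' `N_i`. Nodes of degree < 2 contribute 0; the network value is the mean
#' over all nodes.
#'
#' @param net a `weighted_network` or symmetric matrix with weights in
#'   `[0, 1]`.
#' @return Scalar local efficiency.
#' @export
local_efficiency <- function(net) {
  w <- as_weight_matrix(net)
  n <- nrow(w)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    dsub <- weighted_shortest_paths(w[nb, nb, drop = FALSE])
    inv <- 1 / dsub
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    wi <- w[i, nb]
    prod3 <- (outer(wi, wi) * inv)^(1 / 3)
    diag(prod3) <- 0
    vals[i] <- sum(prod3) / (k * (k - 1L))
  }
  mean(vals)
}

#' Area under a metric curve over the sparsity axis
#'
#' Trapezoidal integral of metric values against the sparsity grid,
#' removing the dependence on any single threshold choice.
#'
#' @param values metric values, one per grid point.
#' @param grid ascending sparsity grid (>= 2 points).
#' @return Scalar AUC.
#' @export
auc_over_sparsity <- function(values, grid) {
  if (length(grid) < 2L) stop("need at least 2 grid points")
  if (length(values) != length(grid))
    stop("values and grid must have equal length")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be ascending")
  pracma::trapz(grid, values)
}

#' Default sparsity grid
#'
#' 15% to 30% in 1% steps (16 levels).
#' @return Numeric vector of length 16.
#' @export
default_sparsity_grid <- function() seq(0.15, 0.30, by = 0.01)

#' Graph-metric profile over a sparsity sweep
#'
#' Thresholds a connectivity matrix at every sparsity level of the grid
#' and computes the four weighted graph metrics (characteristic path
#' length, clustering coefficient, global and local efficiency), then
#' aggregates each metric by its area under the curve over sparsity.
#'
#' @param mat symmetric connectivity matrix (window-averaged PLI).
#' @param grid ascending sparsity grid, default [default_sparsity_grid()].
#' @return An object of class `network_feature_profile`: list with
#'   `profile` (data.frame: sparsity, Lw, Cw, Eglobal, Elocal,
#'   disconnected) and `auc` (named numeric of the four per-metric AUCs).
#' @export
sparsity_sweep <- function(mat, grid = default_sparsity_grid()) {
  if (!length(grid)) stop("grid must be nonempty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be ascending")
  rows <- lapply(grid, function(s) {
    net <- proportional_threshold(mat, s)
    lw <- characteristic_path_length(net)
    data.frame(sparsity = s, Lw = as.numeric(lw),
               Cw = weighted_clustering(net),
               Eglobal = global_efficiency(net),
               Elocal = local_efficiency(net),
               disconnected = attr(lw, "disconnected"))
  })
  profile <- do.call(rbind, rows)
  auc <- vapply(c("Lw", "Cw", "Eglobal", "Elocal"), function(m)
    auc_over_sparsity(profile[[m]], grid), numeric(1L))
  structure(list(profile = profile, auc = auc),
            class = "network_feature_profile")
}
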