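validate_adjacency <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) abort("adjacency matrix must be square")
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10))) {
    abort("adjacency matrix must be symmetric")
  }
  if (any(diag(W) != 0)) abort("adjacency diagonal must be zero")
  if (any(W < 0)) abort("adjacency weights must be non-negative")
  W
}

#' Mean weighted clustering coefficient
#'
#' Per node `i`: `C_i = sum_{k,l} w_ik w_il w_kl / sum_{k != l} w_ik w_il`
#' (triple products over distinct neighbours), with `C_i = 0` when the
#' denominator vanishes; the result is the mean over nodes. For weights in
#' \[0, 1\] the coefficient lies in \[0, 1\].
#'
#' @param W Symmetric weighted adjacency matrix with zero diagonal.
#' @return Scalar mean clustering coefficient.
#' @export
weighted_clustering <- function(W) {
  W <- validate_adjacency(W)
  num <- diag(W %*% W %*% W)
  s <- rowSums(W)
  den <- s^2 - rowSums(W^2)
  ci <- ifelse(den > 0, num / den, 0)
  mean(ci)
}

#' Mean weighted shortest path length
#'
#' Edge lengths are `1/w` (absent edge for `w = 0`); all-pairs shortest
#' paths by Dijkstra's algorithm. If every pair is connected, the mean over
#' unordered pairs is returned; otherwise the harmonic-mean convention
#' `Lw = 1 / mean(1/d_ij)` with `1/Inf = 0` is used.
#'
#' @param W Symmetric weighted adjacency matrix with zero diagonal.
#' @return Scalar mean path length.
#' @export
weighted_path_length <- function(W) {
  W <- validate_adjacency(W)
  r <- nrow(W)
  if (r < 2) abort("path length undefined for a single-node graph")
  g <- adjacency_graph(W)
  D <- igraph::distances(g, weights = igraph::E(g)$length,
                         algorithm = "dijkstra")
  d <- D[upper.tri(D)]
  if (all(is.finite(d))) mean(d) else 1 / mean(1 / d)
}

adjacency_graph <- function(W) {
  r <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = r, directed = FALSE)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, as.vector(t(idx)))
    igraph::E(g)$length <- 1 / W[idx]
    igraph::E(g)$weight <- W[idx]
  }
  g
}

#' Newman modularity by simulated annealing
#'
#' Weighted Newman modularity
#' `Q = (1/2m) sum_ij (w_ij - s_i s_j / 2m) d(c_i, c_j)` maximized by
#' simulated annealing (random initial partition; proposals move one node to
#' another -- possibly new -- module; initial temperature `t0`, geometric
#' cooling per proposal, stop when the temperature falls below `t_min` or
#' after `100 * R` consecutive rejections). The annealed Q and module count
#' are averaged over `n_runs` independent runs, mirroring the 100-run
#' averaging used to stabilise the measure.
#'
#' @param W Symmetric weighted adjacency matrix with zero diagonal.
#' @param n_runs Number of annealing runs to average (default 100).
#' @param seed Integer seed; results are deterministic per seed.
#' @param t0,cooling,t_min Annealing schedule (defaults 1, 0.995, 1e-4).
#' @return A list with `q_mean`, `n_modules_mean`, and the per-run vectors
#'   `q_runs`, `module_runs`.
#' @export
modularity_anneal <- function(W, n_runs = 100, seed, t0 = 1,
                              cooling = 0.995, t_min = 1e-4) {
  W <- validate_adjacency(W)
  stopifnot(n_runs >= 1)
  if (missing(seed)) abort("`seed` is required")
  if (sum(W) <= 0) abort("empty graph: all-zero adjacency")
  res <- local_seed(seed, {
    anneal_modularity_cpp(W, as.integer(n_runs), t0, cooling, t_min,
                          as.integer(100 * nrow(W)))
  })
  list(q_mean = mean(res$q), n_modules_mean = mean(res$n_modules),
       q_runs = as.numeric(res$q), module_runs = as.integer(res$n_modules))
}

#' Modularity of a given partition
#'
#' @param W Symmetric weighted adjacency matrix with zero diagonal.
#' @param membership Integer module label per node.
#' @return Scalar Q (<= 1; 0 for the single-module partition).
#' @export
modularity_q <- function(W, membership) {
  W <- validate_adjacency(W)
  two_m <- sum(W)
  if (two_m <= 0) abort("empty graph: all-zero adjacency")
  s <- rowSums(W)
  q <- 0
  for (m in unique(membership)) {
    in_m <- membership == m
    q <- q + sum(W[in_m, in_m]) / two_m - (sum(s[in_m]) / two_m)^2
  }
  q
}

#' Minimum spanning tree by Kruskal's algorithm
#'
#' Edge lengths are `1/w` (edges with `w = 0` are absent); ties are broken
#' deterministically by (length, smaller node id, larger node id).
#'
#' @param W Symmetric weighted adjacency matrix with zero diagonal; the
#'   positive-weight graph must be connected.
#' @return An object of class `meg_mst`: `edges` tibble (i, j, weight,
#'   length), `n_nodes`.
#' @export
minimum_spanning_tree <- function(W) {
  W <- validate_adjacency(W)
  r <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(idx) < r - 1) abort("disconnected graph: no spanning tree exists")
  len <- 1 / W[idx]
  ord <- order(len, idx[, 1], idx[, 2])
  parent <- seq_len(r)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(0)
  for (e in ord) {
    ri <- find(idx[e, 1]); rj <- find(idx[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      keep <- c(keep, e)
      if (length(keep) == r - 1) break
    }
  }
  if (length(keep) < r - 1) abort("disconnected graph: no spanning tree exists")
  structure(list(
    edges = tibble::tibble(i = as.integer(idx[keep, 1]),
                           j = as.integer(idx[keep, 2]),
                           weight = W[idx[keep, , drop = FALSE]],
                           length = len[keep]),
    n_nodes = r), class = "meg_mst")
}

#' Degree, leaf fraction and diameter of a spanning tree
#'
#' @param tree A [minimum_spanning_tree()] result.
#' @return A list: `degree` (integer per node), `leaf_fraction`
#'   (fraction of degree-one nodes), `diameter` (longest hop distance).
#' @export
mst_metrics <- function(tree) {
  stopifnot(inherits(tree, "meg_mst"))
  r <- tree$n_nodes
  deg <- tabulate(c(tree$edges$i, tree$edges$j), nbins = r)
  g <- igraph::make_graph(rbind(tree$edges$i, tree$edges$j), n = r,
                          directed = FALSE)
  D <- igraph::distances(g, weights = NA)
  list(degree = as.integer(deg),
       leaf_fraction = mean(deg == 1),
       diameter = as.integer(max(D)))
}

#' All global network metrics of one adjacency matrix
#'
#' @param W Symmetric weighted adjacency matrix with zero diagonal.
#' @param modularity_runs Annealing runs for modularity.
#' @param seed Seed for the modularity annealing.
#' @return A one-row tibble with `pli` (mean upper-triangle weight), `cw`,
#'   `lw`, `q`, `n_modules`, `leaf_fraction`, `diameter`, plus the MST degree
#'   vector as a list column `mst_degree`.
#' @export
network_metrics <- function(W, modularity_runs = 100, seed) {
  W <- validate_adjacency(W)
  mst <- minimum_spanning_tree(W)
  mm <- mst_metrics(mst)
  mod <- modularity_anneal(W, n_runs = modularity_runs, seed = seed)
  tibble::tibble(
    pli = mean(W[upper.tri(W)]),
    cw = weighted_clustering(W),
    lw = weighted_path_length(W),
    q = mod$q_mean,
    n_modules = mod$n_modules_mean,
    leaf_fraction = mm$leaf_fraction,
    diameter = mm$diameter,
    mst_degree = list(mm$degree))
}
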