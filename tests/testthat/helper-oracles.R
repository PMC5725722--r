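# Independent oracles used to freeze expected values. These deliberately use
# different algorithms / code paths than the package implementation.

# Floyd-Warshall all-pairs shortest paths on edge lengths 1/w.
fw_distances <- function(W) {
  r <- nrow(W)
  D <- matrix(Inf, r, r)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(r)) {
    for (i in seq_len(r)) {
      for (j in seq_len(r)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Decode a Pruefer sequence into the r-1 edges of a labelled tree on 1..r.
prufer_decode <- function(p, r) {
  deg <- rep(1L, r)
  for (x in p) deg[x] <- deg[x] + 1L
  edges <- matrix(0L, r - 1, 2)
  for (k in seq_along(p)) {
    leaf <- which(deg == 1L)[1]
    edges[k, ] <- c(leaf, p[k])
    deg[leaf] <- 0L
    deg[p[k]] <- deg[p[k]] - 1L
  }
  edges[r - 1, ] <- which(deg == 1L)
  edges
}

# All labelled spanning trees of K_r as an (r^(r-2)) x (r-1) matrix of
# edge-pair indices into the upper triangle (Cayley enumeration). Cached per r.
all_trees_cache <- new.env()
all_spanning_trees <- function(r) {
  key <- as.character(r)
  if (!is.null(all_trees_cache[[key]])) return(all_trees_cache[[key]])
  pair_index <- matrix(0L, r, r)
  ut <- which(upper.tri(pair_index))
  pair_index[ut] <- seq_along(ut)
  pair_index <- pair_index + t(pair_index)
  trees <- if (r == 2) {
    matrix(pair_index[1, 2], 1, 1)
  } else {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(r)), r - 2)))
    t(apply(seqs, 1, function(p) {
      e <- prufer_decode(as.integer(p), r)
      pair_index[cbind(e[, 1], e[, 2])]
    }))
  }
  all_trees_cache[[key]] <- trees
  trees
}

# Exhaustive minimum over all spanning trees of the complete graph, using
# edge lengths 1/w. Requires all weights > 0.
mst_bruteforce_length <- function(W) {
  r <- nrow(W)
  len <- (1 / W)[upper.tri(W)]
  trees <- all_spanning_trees(r)
  min(rowSums(matrix(len[trees], nrow(trees))))
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, k, maxm) {
    if (k > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (m in seq_len(maxm + 1)) {
      memb[k] <- m
      rec(memb, k + 1, max(maxm, m))
    }
  }
  rec(integer(n), 1, 0)
  out
}

# Exact maximum modularity by partition enumeration (small n only).
max_modularity_exact <- function(W) {
  parts <- all_partitions(nrow(W))
  qs <- vapply(parts, function(m) modularity_q(W, m), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# ICC(3,1) via stats::aov two-way decomposition (independent of icc31()).
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(value = c(a, b),
                   item = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(value ~ item + rater, data = df))[[1]]
  msr <- tab["item", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse)
}

# Hop-count diameter of a tree by repeated breadth-first search.
bfs_diameter <- function(edges, r) {
  adj <- vector("list", r)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  bfs <- function(s) {
    d <- rep(-1L, r); d[s] <- 0L; q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (u in adj[[v]]) if (d[u] < 0) { d[u] <- d[v] + 1L; q <- c(q, u) }
    }
    d
  }
  max(vapply(seq_len(r), function(s) max(bfs(s)), integer(1)))
}

# Random symmetric adjacency with strictly positive weights (complete graph).
random_full_adjacency <- function(r) {
  W <- matrix(0, r, r)
  W[upper.tri(W)] <- runif(r * (r - 1) / 2, 0.05, 1)
  W + t(W)
}

# Random sparse-ish adjacency, possibly with zero-weight (absent) edges.
random_sparse_adjacency <- function(r, p_edge = 0.7) {
  W <- matrix(0, r, r)
  m <- r * (r - 1) / 2
  w <- runif(m, 0.05, 1) * (runif(m) < p_edge)
  W[upper.tri(W)] <- w
  W + t(W)
}
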