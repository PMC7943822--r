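# Independent oracles used across the suite. Each is a direct, brute-force
# or closed-form computation kept deliberately separate from the package's
# own code paths.

# named random expression matrix
rand_expr <- function(n_genes, n_samples, seed = 1, positive = FALSE) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (positive) v <- exp(v) else v
}

half_half_groups <- function(sample_ids) {
  n <- length(sample_ids)
  sample_groups(setNames(c(rep("tumor", ceiling(n / 2)),
                           rep("normal", floor(n / 2))), sample_ids))
}

# modularity straight from the defining double sum over ordered pairs
modularity_direct <- function(graph, labels) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  k <- rowSums(A)
  m <- sum(k) / 2
  lab <- as.integer(factor(labels))
  same <- outer(lab, lab, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

# enumerate all set partitions of n items as restricted growth strings and
# return the maximum modularity over them
exhaustive_best_q <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  k <- rowSums(A)
  m <- sum(k) / 2
  Bvec <- as.vector(A - outer(k, k) / (2 * m))
  ri <- rep(seq_len(n), times = n)
  ci <- rep(seq_len(n), each = n)
  best <- -Inf
  a <- rep(1L, n)     # restricted growth string
  b <- rep(1L, n)     # running maxima
  repeat {
    q <- sum(Bvec[a[ri] == a[ci]]) / (2 * m)
    if (q > best) best <- q
    # next restricted growth string
    i <- n
    while (i > 1L && a[i] == b[i] + 1L) i <- i - 1L
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) {
      for (j in (i + 1L):n) {
        b[j] <- max(b[j - 1L], a[j - 1L])
        a[j] <- 1L
      }
    }
  }
  best
}

# random connected graph on n nodes: random spanning tree + extra edges
rand_connected_graph <- function(n, extra_p = 0.3, seed = 1) {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  pairs <- t(utils::combn(n, 2L))
  extra <- pairs[runif(nrow(pairs)) < extra_p, , drop = FALSE]
  el <- unique(rbind(t(apply(edges, 1L, sort)), extra))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# PageRank by solving the stationary linear system directly
pagerank_solve <- function(graph, damping = 0.85) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  out_w <- rowSums(A)
  dangling <- out_w == 0
  M <- t(A / ifelse(out_w == 0, 1, out_w))
  # dangling nodes distribute uniformly
  M[, dangling] <- 1 / n
  x <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  setNames(x / sum(x), igraph::V(graph)$name)
}

# AUC by exhaustive pair comparison (ties count half)
auc_pairs <- function(values, is_tumor) {
  xt <- values[is_tumor]
  xn <- values[!is_tumor]
  tot <- 0
  for (a in xt) for (b in xn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xt) * length(xn))
}

# two-group logrank chi-square assembled from the O-E/variance formula
logrank_direct <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    e1 <- d_tot * n1 / n_tot
    o_minus_e <- o_minus_e + d1 - e1
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  if (v == 0) return(1)
  pchisq(o_minus_e^2 / v, df = 1, lower.tail = FALSE)
}

# adjusted Rand index over two label vectors
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
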