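# Modularity-maximizing community detection by recursive spectral bisection
# (leading eigenvector of the modularity matrix) with Kernighan-Lin-style
# single-node sweep refinement. This stage supplies the cluster count K and
# the seed eigengenes for the K-means refinement.

#' Newman-Girvan modularity of a labeling
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)` on the
#' unweighted graph (an edge either exists or not). Equivalently
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` over communities, with `e_c` internal
#' edges and `d_c` the community degree sum.
#'
#' @param graph undirected [igraph::graph] with at least one edge.
#' @param membership community labels, one per vertex (any label type); named
#'   vectors are matched to vertex names.
#' @return modularity Q (unitless, at most 1).
#' @export
modularity_q <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0L) stop("modularity is undefined on an edgeless graph")
  vn <- igraph::V(graph)$name
  if (!is.null(names(membership)) && !is.null(vn)) {
    missing <- setdiff(vn, names(membership))
    if (length(missing)) {
      stop(sprintf("no community label for vertex '%s'", missing[1L]))
    }
    membership <- membership[vn]
  }
  if (length(membership) != igraph::vcount(graph)) {
    stop("membership length must equal the vertex count")
  }
  lab <- as.integer(factor(membership))
  el <- igraph::as_edgelist(graph, names = FALSE)
  e_c <- tabulate(lab[el[, 1L]][lab[el[, 1L]] == lab[el[, 2L]]],
                  nbins = max(lab))
  deg <- igraph::degree(graph)
  d_c <- tapply(deg, lab, sum)
  sum(e_c / m) - sum((as.numeric(d_c) / (2 * m))^2)
}

# Q contribution of a +/-1 split on the generalized modularity matrix:
# dQ = s' B s / (4m)
.split_gain <- function(B, s, m) {
  drop(crossprod(s, B %*% s)) / (4 * m)
}

# Kernighan-Lin single-node sweep refinement of a +/-1 split. Each sweep
# moves every node exactly once (greedy best move, even when negative) and
# keeps the best intermediate state; sweeps repeat while they improve.
.kl_refine <- function(B, s, m) {
  n <- length(s)
  best_q <- .split_gain(B, s, m)
  repeat {
    s_work <- s
    bs <- drop(B %*% s_work)
    q_run <- best_q
    sweep_best_q <- best_q
    sweep_best_s <- s
    unmoved <- rep(TRUE, n)
    for (step in seq_len(n)) {
      # gain from flipping node i: -4 s_i ((Bs)_i - B_ii s_i) / 4m
      gains <- (-4 * s_work * (bs - diag(B) * s_work)) / (4 * m)
      gains[!unmoved] <- -Inf
      i <- which.max(gains)
      q_run <- q_run + gains[i]
      bs <- bs - 2 * s_work[i] * B[, i]
      s_work[i] <- -s_work[i]
      unmoved[i] <- FALSE
      if (q_run > sweep_best_q + 1e-13) {
        sweep_best_q <- q_run
        sweep_best_s <- s_work
      }
    }
    if (sweep_best_q > best_q + 1e-13) {
      best_q <- sweep_best_q
      s <- sweep_best_s
    } else {
      break
    }
  }
  list(s = s, dq = best_q)
}

# Spectral bisection of the node set `idx` (indices into the full graph).
# B_full is the full modularity matrix A - k k'/2m; the generalized matrix
# for the subgraph is B[g,g] with the row sums subtracted from the diagonal.
.leading_eigen_bisect <- function(B_full, idx, m) {
  Bg <- B_full[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  eig <- eigen(Bg, symmetric = TRUE)
  lead <- eig$values[1L]
  if (lead <= 1e-12) {
    return(list(s = rep(1, length(idx)), dq = 0, indivisible = TRUE))
  }
  v <- eig$vectors[, 1L]
  s <- ifelse(v >= 0, 1, -1)  # exact zeros join the +1 side
  ref <- .kl_refine(Bg, s, m)
  if (ref$dq <= 1e-12 || length(unique(ref$s)) == 1L) {
    return(list(s = s, dq = ref$dq, indivisible = TRUE))
  }
  list(s = ref$s, dq = ref$dq, indivisible = FALSE)
}

#' Detect communities by recursive leading-eigenvector bisection
#'
#' Each connected component of the (unweighted) network is recursively
#' bisected by the sign pattern of the leading eigenvector of the generalized
#' modularity matrix, refined by a Kernighan-Lin node sweep, until no split
#' increases modularity. Isolated nodes (degree 0) are set aside and reported
#' separately; they re-enter at the K-means assignment stage downstream.
#'
#' @param graph undirected [igraph::graph] (e.g. from [build_gcn()]).
#' @return list with `membership` (named integer labels `1..K` over
#'   non-isolated vertices), `K`, `Q` (modularity of the final labeling) and
#'   `isolated` (names of degree-0 vertices).
#' @export
detect_communities <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty network")
  deg <- igraph::degree(graph)
  isolated <- igraph::V(graph)$name[deg == 0L]
  core <- igraph::induced_subgraph(graph, which(deg > 0L))
  n <- igraph::vcount(core)
  if (n == 0L) {
    return(list(membership = setNames(integer(0L), character(0L)),
                K = 0L, Q = NA_real_, isolated = isolated))
  }
  A <- as.matrix(igraph::as_adjacency_matrix(core, sparse = TRUE))
  A[A > 1] <- 1
  k <- rowSums(A)
  m <- sum(k) / 2
  B_full <- A - outer(k, k) / (2 * m)

  labels <- integer(n)
  next_label <- 0L
  comp <- igraph::components(core)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    stack <- list(members)
    while (length(stack)) {
      idx <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (length(idx) < 2L) {
        next_label <- next_label + 1L
        labels[idx] <- next_label
        next
      }
      sp <- .leading_eigen_bisect(B_full, idx, m)
      if (sp$indivisible) {
        next_label <- next_label + 1L
        labels[idx] <- next_label
      } else {
        stack <- c(stack, list(idx[sp$s > 0]), list(idx[sp$s < 0]))
      }
    }
  }
  membership <- setNames(labels, igraph::V(core)$name)
  list(membership = membership,
       K = length(unique(labels)),
       Q = modularity_q(core, membership),
       isolated = isolated)
}
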