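# Co-expression network construction: pairwise Pearson correlation with a
# magnitude threshold and a per-pair significance requirement.

#' All-pairs Pearson correlation with significance
#'
#' Correlates every pair of gene expression profiles across samples. The
#' two-sided p-value uses the exact t-transform
#' `t = r * sqrt(m - 2) / sqrt(1 - r^2)` with `m - 2` degrees of freedom;
#' pairs with `|r| = 1` get p = 0.
#'
#' @param expr expression matrix (genes x samples), at least 3 samples, every
#'   gene with non-zero variance.
#' @return `correlation_result` object: list with symmetric matrices `r` and
#'   `p` and the sample count `n_samples`.
#' @export
pairwise_pearson <- function(expr) {
  validate_expression_matrix(expr)
  m <- ncol(expr)
  if (m < 3L) stop("pairwise correlation needs at least 3 samples")
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    stop(sprintf("gene '%s' has zero variance; filter constant genes first",
                 rownames(expr)[sds == 0][1L]), call. = FALSE)
  }
  r <- cor(t(expr))
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- abs(r) * sqrt(m - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(tstat, df = m - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(r) <- 1
  diag(p) <- 0
  structure(list(r = r, p = p, n_samples = m), class = "correlation_result")
}

#' Build the gene co-expression network
#'
#' An edge joins genes i and j when `|r_ij| >= threshold` and
#' `p_ij < alpha`. Edge weight is `|r|`; the correlation sign is kept as edge
#' metadata. Every input gene is a node, so genes failing every pairwise test
#' remain as isolated nodes.
#'
#' @param cor_result result of [pairwise_pearson()].
#' @param threshold minimum `|r|` for an edge (default 0.65).
#' @param alpha significance cutoff on the correlation p-value (default
#'   0.05).
#' @param bonferroni apply Bonferroni correction over the number of tested
#'   pairs before comparing with `alpha` (off by default; the per-pair rule
#'   is the method's stated construction).
#' @return undirected [igraph::graph] with edge attributes `weight` (`|r|`),
#'   `r` and `sign`, and graph attributes `threshold` and `alpha`.
#' @export
build_gcn <- function(cor_result, threshold = 0.65, alpha = 0.05,
                      bonferroni = FALSE) {
  stopifnot(inherits(cor_result, "correlation_result"))
  r <- cor_result$r
  p <- cor_result$p
  n <- nrow(r)
  n_pairs <- n * (n - 1) / 2
  p_eff <- if (bonferroni) pmin(p * n_pairs, 1) else p
  adj <- abs(r) >= threshold & p_eff < alpha
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- rownames(r)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(rownames(r)[idx[, 1L]],
                                    rownames(r)[idx[, 2L]]))
    rv <- r[idx]
    igraph::E(g)$weight <- abs(rv)
    igraph::E(g)$r <- rv
    igraph::E(g)$sign <- ifelse(rv >= 0, 1L, -1L)
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  igraph::set_graph_attr(g, "alpha", alpha)
}

#' Write a co-expression network as an edge-list TSV
#'
#' Columns: `gene1`, `gene2`, `r` (signed correlation), `weight` (`|r|`).
#'
#' @param gcn graph from [build_gcn()].
#' @param path output path.
#' @export
write_gcn_edges <- function(gcn, path) {
  el <- igraph::as_edgelist(gcn)
  df <- data.frame(gene1 = el[, 1L], gene2 = el[, 2L],
                   r = if (igraph::ecount(gcn)) igraph::E(gcn)$r else numeric(0),
                   weight = if (igraph::ecount(gcn)) igraph::E(gcn)$weight else numeric(0),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
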