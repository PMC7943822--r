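# Key-gene identification: pick the module with the highest biological
# significance, induce the supplied PPI network on its genes, and rank the
# genes by PageRank.

#' Select the key module
#'
#' The module with the highest biological significance `Sig_i`; exact ties
#' go to the lowest module id.
#'
#' @param enrichment `enrichment_report` from [biological_significance()].
#' @return integer module id.
#' @export
select_key_module <- function(enrichment) {
  stopifnot(inherits(enrichment, "enrichment_report"))
  if (!length(enrichment$sig_i)) stop("enrichment report covers no module")
  unname(which.max(enrichment$sig_i))  # which.max takes the first maximum
}

#' PageRank scores on an undirected network
#'
#' Power iteration with uniform teleportation. Undirected edges act as two
#' directed edges; isolated (dangling) nodes redistribute their mass
#' uniformly. Converges when the L1 change falls below `tol`.
#'
#' @param graph [igraph::graph] with at least one vertex.
#' @param damping damping factor (default 0.85).
#' @param weighted use the `score` edge attribute as transition weights
#'   (default `FALSE`: every edge counts equally).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return named numeric scores summing to 1.
#' @export
pagerank <- function(graph, damping = 0.85, weighted = FALSE,
                     tol = 1e-10, max_iter = 1000L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("PageRank needs at least one vertex")
  nm <- igraph::V(graph)$name %||% as.character(seq_len(n))
  if (n == 1L) return(setNames(1, nm))
  A <- igraph::as_adjacency_matrix(
    graph, sparse = FALSE,
    attr = if (weighted && "score" %in% igraph::edge_attr_names(graph)) "score"
           else NULL)
  A[A < 0] <- 0
  out_w <- rowSums(A)
  dangling <- out_w == 0
  # column-stochastic transition matrix over non-dangling rows
  M <- t(A / ifelse(out_w == 0, 1, out_w))
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- damping * (M %*% x + sum(x[dangling]) / n) + (1 - damping) / n
    x_new <- drop(x_new)
    if (sum(abs(x_new - x)) < tol) {
      return(setNames(x_new / sum(x_new), nm))
    }
    x <- x_new
  }
  stop(sprintf("PageRank did not converge in %d iterations (residual %.3e)",
               max_iter, sum(abs(x_new - x))))
}

#' Rank a key module's genes by PageRank on the PPI subnetwork
#'
#' Induces the supplied PPI network on the key module's genes, runs
#' [pagerank()] on the induced subnetwork, and returns the top `k` genes.
#' Module genes absent from the PPI node set are excluded (with a message);
#' when fewer than `k` genes can be ranked the full list is returned with a
#' warning.
#'
#' @param partition [module_partition()].
#' @param key_module integer module id (e.g. from [select_key_module()]).
#' @param ppi undirected PPI [igraph::graph] (e.g. from [read_edge_list()]).
#' @param k number of key genes (default 10).
#' @param damping,weighted passed to [pagerank()].
#' @return `key_gene_result`: list with `key_module`, `scores` (all ranked
#'   genes) and `top` (ordered top-k gene ids; ties broken by gene id).
#' @export
top_key_genes <- function(partition, key_module, ppi, k = 10L,
                          damping = 0.85, weighted = FALSE) {
  stopifnot(inherits(partition, "module_partition"))
  module_genes <- names(partition$labels)[partition$labels == key_module]
  if (!length(module_genes)) stop(sprintf("module %d has no genes", key_module))
  present <- intersect(module_genes, igraph::V(ppi)$name)
  absent <- setdiff(module_genes, present)
  if (length(absent)) {
    message(sprintf("%d module gene(s) absent from the PPI network: %s",
                    length(absent), paste(absent, collapse = ", ")))
  }
  if (!length(present)) stop("no module gene is present in the PPI network")
  sub <- igraph::induced_subgraph(ppi, present)
  scores <- pagerank(sub, damping = damping, weighted = weighted)
  ord <- order(-scores, names(scores))
  ranked <- scores[ord]
  if (length(ranked) < k) {
    warning(sprintf("only %d gene(s) available in the induced PPI subnetwork; returning all",
                    length(ranked)))
  }
  structure(list(key_module = key_module,
                 scores = ranked,
                 top = names(ranked)[seq_len(min(k, length(ranked)))]),
            class = "key_gene_result")
}

#' @export
print.key_gene_result <- function(x, ...) {
  cat(sprintf("key_gene_result: module %d, top %d genes\n",
              x$key_module, length(x$top)))
  print(round(x$scores[x$top], 5))
  invisible(x)
}
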