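# The eigengene-seeded K-means core: module eigengene (first principal
# component) centers, correlation distance D(g, C) = 1 - |cor(g, C)|,
# nearest-center assignment, PCA center update, and the outer refinement
# loop seeded by the community-detection partition.

#' K-means loop configuration
#'
#' @param max_iter maximum assign/update iterations (default 100).
#' @param min_module_size smallest cluster kept alive during updates
#'   (default 3, minimum 2; a single-gene cluster's eigengene is just the
#'   gene's own standardized profile, so clusters this small carry no
#'   summary value).
#' @param seed integer seed recorded with the run (the loop itself is
#'   deterministic; the seed covers any randomized caller).
#' @return `kpca_config` list.
#' @export
kpca_config <- function(max_iter = 100L, min_module_size = 3L,
                        seed = .default_seed) {
  stopifnot(max_iter >= 1L, min_module_size >= 2L)
  structure(list(max_iter = as.integer(max_iter),
                 min_module_size = as.integer(min_module_size),
                 seed = as.integer(seed)),
            class = "kpca_config")
}

#' Module eigengene: first principal component of a gene set
#'
#' Each member gene's profile is standardized to mean 0, sd 1 across samples;
#' the eigengene is the first right singular vector of the standardized
#' matrix, i.e. the per-sample summary profile explaining the most variance.
#' It has unit Euclidean norm and its sign is fixed so that it correlates
#' non-negatively with the mean standardized profile; when that correlation
#' is undefined (exactly balanced positive and negative loadings) the first
#' non-zero coordinate is made positive.
#'
#' @param expr_sub expression matrix rows of one module (>= 1 gene, no
#'   constant gene).
#' @return numeric eigengene vector, one value per sample, unit norm.
#' @export
compute_eigengene <- function(expr_sub) {
  if (is.null(dim(expr_sub))) expr_sub <- matrix(expr_sub, nrow = 1L)
  sds <- apply(expr_sub, 1L, sd)
  if (any(sds == 0)) {
    bad <- rownames(expr_sub)[sds == 0][1L] %||% "<unnamed>"
    stop(sprintf("gene '%s' is constant across samples; eigengene undefined",
                 bad), call. = FALSE)
  }
  z <- (expr_sub - rowMeans(expr_sub)) / sds
  me <- svd(z, nu = 0L, nv = 1L)$v[, 1L]
  me <- me / sqrt(sum(me^2))
  cm <- colMeans(z)
  ori <- sum(me * (cm - mean(cm)))
  if (abs(ori) > 1e-12) {
    if (ori < 0) me <- -me
  } else {
    nz <- which(abs(me) > 1e-12)[1L]
    if (!is.na(nz) && me[nz] < 0) me <- -me
  }
  setNames(me, colnames(expr_sub))
}

#' Correlation distance between a gene and a cluster center
#'
#' `D(g, C) = 1 - |cor(g, C)|`, so perfectly correlated and perfectly
#' anti-correlated profiles are both at distance 0.
#'
#' @param g gene expression vector.
#' @param center cluster-center vector of the same length.
#' @return distance in \[0, 1\].
#' @export
correlation_distance <- function(g, center) {
  if (length(g) != length(center)) stop("vectors must have equal length")
  if (sd(g) == 0 || sd(center) == 0) {
    stop("correlation distance is undefined for a constant vector")
  }
  1 - abs(cor(g, center))
}

# genes x centers matrix of correlation distances
.distance_matrix <- function(expr, centers) {
  d <- 1 - abs(suppressWarnings(cor(t(expr), t(centers))))
  d[is.na(d)] <- 1
  d
}

#' Assign every gene to its nearest cluster center
#'
#' Nearest in correlation distance; exact ties go to the lowest center index.
#'
#' @param expr expression matrix (genes x samples).
#' @param centers K x samples matrix of cluster centers (module eigengenes).
#' @return named integer labels in `1..K`.
#' @export
assign_genes <- function(expr, centers) {
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1L)
  if (nrow(centers) < 1L) stop("at least one cluster center is required")
  d <- .distance_matrix(expr, centers)
  setNames(apply(d, 1L, which.min), rownames(expr))
}

#' Recompute cluster centers as module eigengenes
#'
#' Each non-empty cluster's center becomes the first principal component of
#' its member genes. Clusters that fall below `min_module_size` are dropped
#' (K decreases); the returned label map records the renumbering.
#'
#' @param expr expression matrix.
#' @param labels named integer cluster labels over the rows of `expr`.
#' @param min_module_size smallest surviving cluster (default 2).
#' @return list with `centers` (K' x samples matrix), `label_map` (named
#'   integer: old label -> new label, dropped labels absent) and `dropped`
#'   (old labels removed).
#' @export
update_centers <- function(expr, labels, min_module_size = 2L) {
  labels <- labels[rownames(expr)]
  sizes <- table(labels)
  keep <- as.integer(names(sizes))[sizes >= min_module_size]
  keep <- sort(keep)
  if (!length(keep)) stop("every cluster fell below min_module_size")
  centers <- t(vapply(keep, function(lab) {
    compute_eigengene(expr[names(labels)[labels == lab], , drop = FALSE])
  }, numeric(ncol(expr))))
  colnames(centers) <- colnames(expr)
  list(centers = centers,
       label_map = setNames(seq_along(keep), keep),
       dropped = setdiff(as.integer(names(sizes)), keep))
}

#' Gene module identification by eigengene-seeded correlation K-means
#'
#' The full module-identification core: build the co-expression network from
#' all-pairs Pearson correlation (`|r| >= threshold`, p < `alpha`), detect
#' communities by recursive leading-eigenvector bisection to fix the cluster
#' count K and the initial eigengene centers, then iterate nearest-center
#' assignment (correlation distance) and PCA center updates until the
#' labeling reaches a fixpoint. Genes isolated in the network enter at the
#' first assignment pass. If the labeling revisits a previous state
#' (oscillation), the loop stops and keeps the visited labeling with the
#' lowest module-membership error rate.
#'
#' @param expr preprocessed expression matrix (genes x samples).
#' @param threshold `|r|` cutoff for network edges (default 0.65).
#' @param alpha significance cutoff for network edges (default 0.05).
#' @param config [kpca_config()] loop controls.
#' @return list with `partition` (a [module_partition()] carrying labels and
#'   final eigengenes), `seed_partition` (the community-detection labeling
#'   over non-isolated genes), `trace` (per-iteration label changes and
#'   cluster counts, `converged`, `n_iter`) and `gcn` (the network).
#' @export
run_gcna_kpca <- function(expr, threshold = 0.65, alpha = 0.05,
                          config = kpca_config()) {
  validate_expression_matrix(expr)
  cres <- pairwise_pearson(expr)
  gcn <- build_gcn(cres, threshold = threshold, alpha = alpha)
  comm <- detect_communities(gcn)
  if (comm$K == 0L) {
    stop("the co-expression network has no edges; lower the correlation threshold",
         call. = FALSE)
  }
  seed_centers <- t(vapply(seq_len(comm$K), function(lab) {
    members <- names(comm$membership)[comm$membership == lab]
    compute_eigengene(expr[members, , drop = FALSE])
  }, numeric(ncol(expr))))
  colnames(seed_centers) <- colnames(expr)

  labels <- assign_genes(expr, seed_centers)
  seen <- list(.label_signature(labels))
  history <- list(labels)
  changes_log <- integer(0L)
  clusters_log <- integer(0L)
  converged <- FALSE
  final_centers <- seed_centers
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    upd <- update_centers(expr, labels, min_module_size = config$min_module_size)
    new_labels <- assign_genes(expr, upd$centers)
    # compare through the renumbering; genes of dropped clusters count as moved
    remapped <- unname(upd$label_map[as.character(labels)])
    changes <- sum(is.na(remapped) | remapped != new_labels)
    changes_log <- c(changes_log, changes)
    clusters_log <- c(clusters_log, nrow(upd$centers))
    final_centers <- upd$centers
    if (changes == 0L) {
      labels <- new_labels
      converged <- TRUE
      break
    }
    sig <- .label_signature(new_labels)
    if (sig %in% unlist(seen)) {
      # oscillation: keep the visited labeling with the lowest error rate
      cand <- c(history, list(new_labels))
      errs <- vapply(cand, function(l) {
        error_rate(module_partition(.canonical_labels(l)), expr)$error_rate
      }, numeric(1L))
      labels <- cand[[which.min(errs)]]
      break
    }
    seen <- c(seen, sig)
    history <- c(history, list(new_labels))
    labels <- new_labels
  }
  labels <- .canonical_labels(labels)
  upd_final <- update_centers(expr, labels, min_module_size = 1L)
  partition <- module_partition(labels, upd_final$centers)
  trace <- list(changes = changes_log, n_clusters = clusters_log,
                n_iter = it, converged = converged)
  list(partition = partition,
       seed_partition = module_partition(.canonical_labels(comm$membership)),
       seed_Q = comm$Q,
       isolated = comm$isolated,
       trace = trace,
       gcn = gcn)
}

# renumber labels to consecutive 1..K in order of first appearance
.canonical_labels <- function(labels) {
  setNames(match(labels, unique(labels)), names(labels))
}

.label_signature <- function(labels) {
  paste(.canonical_labels(labels), collapse = ",")
}
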