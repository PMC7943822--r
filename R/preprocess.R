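# Expression preprocessing: the four upstream filters applied before network
# construction -- low-expression removal, dendrogram-based sample outlier
# removal, fold-change selection and per-gene Welch t-test selection.

#' Remove low-expression genes
#'
#' A gene is retained when its maximum expression reaches `min_max` in at
#' least one of the two groups; genes unexpressed in both groups are removed.
#' Setting `require_both = TRUE` switches to the stricter reading under which
#' a gene must reach the threshold in both groups.
#'
#' @param expr expression matrix (genes x samples).
#' @param groups named factor of `tumor`/`normal` labels.
#' @param min_max minimum of the per-group maximum expression (default 1, the
#'   conventional FPKM floor).
#' @param require_both require the threshold in both groups instead of either.
#' @return filtered expression matrix.
#' @export
filter_low_expression <- function(expr, groups, min_max = 1, require_both = FALSE) {
  validate_expression_matrix(expr)
  gs <- .group_samples(expr, groups)
  max_t <- apply(expr[, gs$tumor, drop = FALSE], 1L, max)
  max_n <- apply(expr[, gs$normal, drop = FALSE], 1L, max)
  keep <- if (require_both) max_t >= min_max & max_n >= min_max
          else max_t >= min_max | max_n >= min_max
  if (!any(keep)) {
    stop(sprintf("no gene passes the low-expression filter at min_max = %g; lower the threshold",
                 min_max), call. = FALSE)
  }
  expr[keep, , drop = FALSE]
}

#' Flag outlier samples by dendrogram merge height
#'
#' Average-linkage hierarchical clustering on the Euclidean distance between
#' sample expression profiles; a sample is flagged when the height at which
#' it first merges into the tree exceeds `mean + z_cut * sd` of all leaf
#' merge heights. The flagged list is advisory -- callers decide what to drop.
#'
#' @param expr expression matrix (genes x samples), at least 3 samples.
#' @param z_cut flag threshold in standard deviations (default 2.5).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(expr, z_cut = 2.5) {
  validate_expression_matrix(expr)
  if (ncol(expr) < 3L) stop("outlier detection needs at least 3 samples")
  hc <- hclust(dist(t(expr)), method = "average")
  # height at which each leaf first merges
  leaf_height <- vapply(seq_len(ncol(expr)), function(leaf) {
    row <- which(hc$merge[, 1L] == -leaf | hc$merge[, 2L] == -leaf)
    hc$height[row]
  }, numeric(1L))
  if (!is.finite(z_cut)) return(character(0L))
  s <- sd(leaf_height)
  if (s == 0) return(character(0L))
  colnames(expr)[leaf_height > mean(leaf_height) + z_cut * s]
}

# per-gene tumor/normal fold change (ratio of group means, pseudocounted)
.fold_change <- function(expr, groups, pseudocount = 1e-3) {
  gs <- .group_samples(expr, groups)
  mt <- rowMeans(expr[, gs$tumor, drop = FALSE])
  mn <- rowMeans(expr[, gs$normal, drop = FALSE])
  (mt + pseudocount) / (mn + pseudocount)
}

#' Retain differentially expressed genes by fold change
#'
#' Fold change is the ratio of the tumor group mean to the normal group mean
#' (raw scale, with a small pseudocount against division by zero). Genes with
#' `FC >= up` (up-regulated) or `FC <= down` (down-regulated) are retained;
#' both bounds are inclusive.
#'
#' @param expr expression matrix.
#' @param groups named factor of `tumor`/`normal` labels.
#' @param up,down retention bounds (defaults 2 and 0.5).
#' @param pseudocount added to both group means (default 1e-3).
#' @return filtered expression matrix with a `fold_change` attribute carrying
#'   the retained genes' fold changes.
#' @export
fold_change_filter <- function(expr, groups, up = 2, down = 0.5,
                               pseudocount = 1e-3) {
  validate_expression_matrix(expr)
  fc <- .fold_change(expr, groups, pseudocount)
  keep <- fc >= up | fc <= down
  out <- expr[keep, , drop = FALSE]
  attr(out, "fold_change") <- fc[keep]
  out
}

# per-gene two-sided Welch t-test p-values; zero variance in both groups -> 1
.welch_p <- function(expr, groups) {
  gs <- .group_samples(expr, groups)
  if (length(gs$tumor) < 2L || length(gs$normal) < 2L) {
    stop("the t-test filter needs at least 2 samples per group")
  }
  xt <- expr[, gs$tumor, drop = FALSE]
  xn <- expr[, gs$normal, drop = FALSE]
  vapply(seq_len(nrow(expr)), function(i) {
    tryCatch(t.test(xt[i, ], xn[i, ])$p.value, error = function(e) 1)
  }, numeric(1L))
}

#' Retain genes differing between groups by Welch t-test
#'
#' Per-gene two-sided Welch (unequal-variance) t-test between the tumor and
#' normal samples; genes with `p < alpha` are retained. Genes with zero
#' variance in both groups are assigned p = 1 and removed. P-values are not
#' multiplicity-corrected.
#'
#' @param expr expression matrix.
#' @param groups named factor of `tumor`/`normal` labels.
#' @param alpha significance cutoff (default 0.05).
#' @return filtered expression matrix with a `p_value` attribute carrying the
#'   retained genes' p-values.
#' @export
t_test_filter <- function(expr, groups, alpha = 0.05) {
  validate_expression_matrix(expr)
  p <- setNames(.welch_p(expr, groups), rownames(expr))
  keep <- p < alpha
  out <- expr[keep, , drop = FALSE]
  attr(out, "p_value") <- p[keep]
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: (1) low-expression removal, (2) sample-outlier removal
#' (flagged by [detect_outlier_samples()] plus any explicit `drop_samples`),
#' (3) fold-change selection, (4) Welch t-test selection. The output gene set
#' shrinks (or stays equal) at every stage.
#'
#' @param expr expression matrix (genes x samples).
#' @param groups named factor of `tumor`/`normal` labels.
#' @param min_max low-expression threshold (step 1).
#' @param outlier_z merge-height z-score for sample flagging (step 2).
#' @param drop_samples explicit sample ids to remove in addition to flagged
#'   outliers.
#' @param fc_up,fc_down fold-change retention bounds (step 3).
#' @param alpha t-test significance cutoff (step 4).
#' @param pseudocount fold-change pseudocount.
#' @return list with `expr` (the filtered matrix) and `report`, a
#'   `preprocess_report` recording per-step removal counts, removed samples,
#'   and the retained genes' fold changes and p-values.
#' @export
preprocess_expression <- function(expr, groups, min_max = 1, outlier_z = 2.5,
                                  drop_samples = character(0L),
                                  fc_up = 2, fc_down = 0.5, alpha = 0.05,
                                  pseudocount = 1e-3) {
  validate_expression_matrix(expr)
  n0 <- nrow(expr)
  e1 <- filter_low_expression(expr, groups, min_max = min_max)
  flagged <- detect_outlier_samples(e1, z_cut = outlier_z)
  removed_samples <- union(flagged, intersect(drop_samples, colnames(e1)))
  e2 <- e1[, setdiff(colnames(e1), removed_samples), drop = FALSE]
  e3 <- fold_change_filter(e2, groups, up = fc_up, down = fc_down,
                           pseudocount = pseudocount)
  e4 <- t_test_filter(e3, groups, alpha = alpha)
  report <- structure(list(
    n_input_genes = n0,
    removed_low_expression = n0 - nrow(e1),
    removed_samples = removed_samples,
    flagged_outliers = flagged,
    removed_fold_change = nrow(e2) - nrow(e3),
    removed_t_test = nrow(e3) - nrow(e4),
    n_output_genes = nrow(e4),
    fold_change = attr(e3, "fold_change")[rownames(e4)],
    p_value = attr(e4, "p_value")
  ), class = "preprocess_report")
  attr(e4, "fold_change") <- NULL
  attr(e4, "p_value") <- NULL
  list(expr = e4, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(paste0(
    "preprocess_report: %d -> %d genes\n",
    "  low expression removed: %d\n",
    "  samples removed: %d (%s)\n",
    "  fold-change removed: %d\n",
    "  t-test removed: %d\n"),
    x$n_input_genes, x$n_output_genes, x$removed_low_expression,
    length(x$removed_samples),
    if (length(x$removed_samples)) paste(x$removed_samples, collapse = ", ")
    else "none",
    x$removed_fold_change, x$removed_t_test))
  invisible(x)
}
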