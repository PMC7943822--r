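# Evaluation metrics for module identification and key genes: the
# module-membership error rate, Fisher-exact biological significance
# (Sig_i and Sig), logrank prognostic significance (Sig_SA), and the
# per-gene tumor/normal ROC AUC.

.clip_p <- function(p) pmax(p, 1e-300)

# per-module significance: sum of -log10(p) over terms below the cutoff
.sig_from_pvalues <- function(p, term_alpha = 0.05) {
  sel <- p < term_alpha
  if (!any(sel)) 0 else sum(-log10(.clip_p(p[sel])))
}

#' Module-membership error rate
#'
#' A gene's module membership `MM_g` is `|cor(g, ME_i)|` with the eigengene
#' of its own module i. Gene g is counted as wrongly assigned when some
#' other module's eigengene correlates strictly more strongly:
#' `|cor(g, ME_j)| > MM_g` for some `j != i` (exact ties are not
#' violations). The error rate is the fraction of violating genes.
#'
#' @param partition [module_partition()]; eigengenes are recomputed from
#'   `expr` when absent.
#' @param expr expression matrix containing every clustered gene.
#' @return `error_rate_report`: list with `mm` (named per-gene module
#'   membership), `violated` (named logical) and `error_rate`.
#' @export
error_rate <- function(partition, expr) {
  stopifnot(inherits(partition, "module_partition"))
  labels <- partition$labels
  missing <- setdiff(names(labels), rownames(expr))
  if (length(missing)) {
    stop(sprintf("clustered gene '%s' is absent from the expression matrix",
                 missing[1L]))
  }
  sub <- expr[names(labels), , drop = FALSE]
  if (partition$K == 1L) {
    warning("single-module partition: error rate is 0 by vacuity")
    mm <- drop(1 - .distance_matrix(sub, rbind(compute_eigengene(sub))))
    return(structure(list(mm = setNames(as.numeric(mm), names(labels)),
                          violated = setNames(rep(FALSE, length(labels)),
                                              names(labels)),
                          error_rate = 0),
                     class = "error_rate_report"))
  }
  eig <- partition$eigengenes
  if (is.null(eig)) {
    eig <- update_centers(sub, labels, min_module_size = 1L)$centers
  }
  ac <- abs(suppressWarnings(cor(t(sub), t(eig))))
  ac[is.na(ac)] <- 0
  own <- ac[cbind(seq_along(labels), labels)]
  best_other <- vapply(seq_along(labels), function(i) {
    max(ac[i, -labels[i]])
  }, numeric(1L))
  violated <- best_other > own
  structure(list(mm = setNames(own, names(labels)),
                 violated = setNames(violated, names(labels)),
                 error_rate = mean(violated)),
            class = "error_rate_report")
}

#' @export
print.error_rate_report <- function(x, ...) {
  cat(sprintf("error_rate_report: %d/%d genes misassigned (error rate %.4f)\n",
              sum(x$violated), length(x$violated), x$error_rate))
  invisible(x)
}

#' Fisher-exact over-representation of annotation terms in a gene set
#'
#' For each term, the one-sided over-representation p-value is the upper
#' tail of the hypergeometric distribution: the probability of drawing at
#' least the observed overlap when `|module|` genes are sampled from the
#' background without replacement. Terms with zero overlap get p = 1.
#'
#' @param module_genes character gene ids (must lie within `background`).
#' @param sets [annotation_sets()].
#' @param background character vector, the enrichment universe.
#' @return data.frame with columns `term`, `overlap`, `p`.
#' @export
fisher_enrichment <- function(module_genes, sets, background) {
  if (!length(background)) stop("empty enrichment background")
  background <- unique(background)
  module_genes <- unique(module_genes)
  outside <- setdiff(module_genes, background)
  if (length(outside)) {
    stop(sprintf("module gene '%s' is not in the enrichment background",
                 outside[1L]))
  }
  n_bg <- length(background)
  n_mod <- length(module_genes)
  res <- lapply(names(sets), function(term) {
    in_bg <- intersect(sets[[term]], background)
    ov <- length(intersect(in_bg, module_genes))
    p <- if (ov == 0L) 1 else {
      phyper(ov - 1L, length(in_bg), n_bg - length(in_bg), n_mod,
             lower.tail = FALSE)
    }
    data.frame(term = term, overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  if (!length(res)) {
    return(data.frame(term = character(0L), overlap = integer(0L),
                      p = numeric(0L)))
  }
  do.call(rbind, res)
}

#' Biological significance of a module partition
#'
#' Per module i, `Sig_i` sums `-log10(p)` over the annotation terms whose
#' Fisher-exact enrichment p-value falls below `term_alpha`; the overall
#' `Sig` is the mean of `Sig_i` over all K modules (modules with no
#' significant term contribute 0). P-values are clipped at 1e-300 before the
#' logarithm and are not multiplicity-corrected.
#'
#' @param partition [module_partition()].
#' @param sets [annotation_sets()].
#' @param background enrichment universe; defaults to the clustered genes.
#' @param term_alpha per-term significance cutoff (default 0.05).
#' @return `enrichment_report`: list with `per_module` (list of enrichment
#'   data.frames), `sig_i` (per-module significance) and `sig` (overall).
#' @export
biological_significance <- function(partition, sets,
                                    background = names(partition$labels),
                                    term_alpha = 0.05) {
  stopifnot(inherits(partition, "module_partition"))
  per_module <- lapply(seq_len(partition$K), function(i) {
    genes <- names(partition$labels)[partition$labels == i]
    fisher_enrichment(intersect(genes, background), sets, background)
  })
  sig_i <- vapply(per_module, function(df) .sig_from_pvalues(df$p, term_alpha),
                  numeric(1L))
  structure(list(per_module = per_module,
                 sig_i = setNames(sig_i, seq_len(partition$K)),
                 sig = mean(sig_i)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("enrichment_report: Sig = %.4f over %d modules\n",
              x$sig, length(x$sig_i)))
  print(round(x$sig_i, 4))
  invisible(x)
}

#' Logrank test after dichotomizing a gene at a quantile
#'
#' Samples are split into low/high expression strata at the gene's
#' `percentile` quantile (ties go to the low stratum) and compared by the
#' standard two-group logrank test (chi-square with 1 df, two-sided).
#'
#' @param gene named expression vector (names are sample ids).
#' @param surv survival table from [survival_table()]; only samples present
#'   in both inputs are used.
#' @param percentile split quantile in (0, 1) (default 0.5, the median).
#' @return two-sided logrank p-value; 1 (with a warning) when every sample
#'   lands in one stratum, and 1 when no events are observed.
#' @export
logrank_by_median <- function(gene, surv, percentile = 0.5) {
  if (is.null(names(gene))) stop("gene expression vector must be named by sample id")
  common <- intersect(names(gene), surv$sample_id)
  if (length(common) < 4L) stop("need at least 4 overlapping samples")
  x <- gene[common]
  st <- surv[match(common, surv$sample_id), ]
  cut <- quantile(x, percentile, names = FALSE, type = 7)
  high <- x > cut
  if (all(high) || all(!high)) {
    warning("all samples fall in one expression stratum; logrank p set to 1")
    return(1)
  }
  if (sum(st$event) == 0L) return(1)
  fit <- survival::survdiff(survival::Surv(st$time, st$event) ~ high)
  unname(pchisq(fit$chisq, df = 1L, lower.tail = FALSE))
}

#' Prognostic significance of a key-gene list
#'
#' `Sig_SA = sum_i -log10(p_i)` over the key genes' logrank p-values
#' (clipped at 1e-300).
#'
#' @param pvalues numeric vector of logrank p-values (at least one).
#' @return Sig_SA (non-negative).
#' @export
prognostic_significance <- function(pvalues) {
  if (!length(pvalues)) stop("at least one p-value is required")
  sum(-log10(.clip_p(pvalues)))
}

#' Tumor/normal discrimination AUC of one gene
#'
#' The area under the ROC curve via the rank-sum (Mann-Whitney)
#' formulation with midrank tie handling; orientation is the probability
#' that a tumor sample's expression exceeds a normal sample's.
#'
#' @param gene named expression vector.
#' @param groups named factor of `tumor`/`normal` labels.
#' @return AUC in \[0, 1\].
#' @export
gene_auc <- function(gene, groups) {
  if (is.null(names(gene))) stop("gene expression vector must be named by sample id")
  g <- groups[names(gene)]
  n1 <- sum(g == "tumor")
  n0 <- sum(g == "normal")
  if (n1 == 0L || n0 == 0L) stop("both tumor and normal samples are required")
  r <- rank(gene)  # midranks for ties
  (sum(r[g == "tumor"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
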