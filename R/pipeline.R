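# File-based pipeline driver: preprocess -> network -> communities ->
# cluster -> evaluate -> keygenes. Stages communicate through files only, so
# each stage is independently inspectable and re-runnable; the exact
# configuration and a per-stage manifest are written next to every output.

#' Pipeline run configuration
#'
#' Collects every stage parameter in one serializable document. Defaults are
#' the method's standard operating point: `|r|` threshold 0.65, significance
#' 0.05, fold-change bounds 2 and 0.5, K-means loop caps, top-10 key genes,
#' PageRank damping 0.85.
#'
#' @param expression,groups paths to the expression matrix and sample-group
#'   table (required).
#' @param gmt,survival,ppi optional input paths; stages needing an absent
#'   input are skipped.
#' @param out_dir output directory.
#' @param min_max,outlier_z,drop_samples,fc_up,fc_down,alpha preprocessing
#'   parameters (see [preprocess_expression()]).
#' @param pcc_threshold,network_alpha network construction parameters.
#' @param max_iter,min_module_size K-means loop controls.
#' @param term_alpha enrichment significance cutoff.
#' @param percentile survival dichotomization quantile.
#' @param k,damping key-gene parameters.
#' @param seed integer seed recorded with the run.
#' @return `run_config` list.
#' @export
run_config <- function(expression, groups, out_dir,
                       gmt = NULL, survival = NULL, ppi = NULL,
                       min_max = 1, outlier_z = 2.5,
                       drop_samples = character(0L),
                       fc_up = 2, fc_down = 0.5, alpha = 0.05,
                       pcc_threshold = 0.65, network_alpha = 0.05,
                       max_iter = 100L, min_module_size = 3L,
                       term_alpha = 0.05, percentile = 0.5,
                       k = 10L, damping = 0.85, seed = .default_seed) {
  structure(list(expression = expression, groups = groups, out_dir = out_dir,
                 gmt = gmt, survival = survival, ppi = ppi,
                 min_max = min_max, outlier_z = outlier_z,
                 drop_samples = drop_samples,
                 fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 pcc_threshold = pcc_threshold, network_alpha = network_alpha,
                 max_iter = as.integer(max_iter),
                 min_module_size = as.integer(min_module_size),
                 term_alpha = term_alpha, percentile = percentile,
                 k = as.integer(k), damping = damping,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full module-identification pipeline
#'
#' Executes preprocess, network construction, community detection, the
#' eigengene K-means refinement, evaluation and key-gene ranking, writing
#' every stage artifact plus a machine-readable manifest and the exact
#' configuration into `config$out_dir`. Stages whose optional inputs (GMT,
#' survival, PPI) are absent are skipped and noted in the manifest.
#'
#' @param config [run_config()].
#' @return the manifest list, invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- res
    res
  }
  set.seed(config$seed)

  expr0 <- read_expression(config$expression)
  groups <- read_sample_groups(config$groups)

  pp <- stage("preprocess", function() {
    out <- preprocess_expression(expr0, groups,
                                 min_max = config$min_max,
                                 outlier_z = config$outlier_z,
                                 drop_samples = config$drop_samples,
                                 fc_up = config$fc_up, fc_down = config$fc_down,
                                 alpha = config$alpha)
    write_expression(out$expr, file.path(config$out_dir, "filtered_expression.tsv"))
    jsonlite::write_json(
      unclass(out$report)[c("n_input_genes", "removed_low_expression",
                            "removed_samples", "removed_fold_change",
                            "removed_t_test", "n_output_genes")],
      file.path(config$out_dir, "preprocess_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    list(genes_in = out$report$n_input_genes,
         genes_out = out$report$n_output_genes,
         samples_removed = out$report$removed_samples,
         expr = out$expr)
  })
  expr <- pp$expr

  fit <- stage("cluster", function() {
    res <- run_gcna_kpca(expr, threshold = config$pcc_threshold,
                         alpha = config$network_alpha,
                         config = kpca_config(max_iter = config$max_iter,
                                              min_module_size = config$min_module_size,
                                              seed = config$seed))
    write_gcn_edges(res$gcn, file.path(config$out_dir, "gcn_edges.tsv"))
    write_partition(res$partition, file.path(config$out_dir, "partition.json"))
    write_partition(res$seed_partition,
                    file.path(config$out_dir, "seed_partition.json"))
    write.table(data.frame(gene_id = names(res$partition$labels),
                           module = unname(res$partition$labels)),
                file.path(config$out_dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$trace, file.path(config$out_dir, "trace.json"),
                         auto_unbox = TRUE, digits = NA)
    list(edges = igraph::ecount(res$gcn), K_seed = res$seed_partition$K,
         seed_Q = res$seed_Q, K = res$partition$K,
         isolated = length(res$isolated),
         iterations = res$trace$n_iter, converged = res$trace$converged,
         fit = res)
  })
  partition <- fit$fit$partition

  eval_res <- stage("evaluate", function() {
    er <- error_rate(partition, expr)
    out <- list(error_rate = er$error_rate)
    if (!is.null(config$gmt)) {
      sets <- read_gmt(config$gmt)
      enr <- biological_significance(partition, sets,
                                     term_alpha = config$term_alpha)
      out$sig <- enr$sig
      out$sig_i <- as.list(enr$sig_i)
      out$enrichment <- enr
    } else {
      out$skipped_sig <- "no GMT file supplied"
    }
    jsonlite::write_json(out[setdiff(names(out), "enrichment")],
                         file.path(config$out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  if (!is.null(config$gmt) && !is.null(config$ppi)) {
    kg <- stage("keygenes", function() {
      ppi <- read_edge_list(config$ppi)
      km <- select_key_module(eval_res$enrichment)
      res <- top_key_genes(partition, km, ppi, k = config$k,
                           damping = config$damping)
      write.table(data.frame(gene_id = names(res$scores),
                             score = unname(res$scores)),
                  file.path(config$out_dir, "key_genes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out <- list(key_module = km, top = res$top)
      if (!is.null(config$survival)) {
        surv <- read_survival(config$survival)
        pvals <- vapply(res$top, function(g) {
          logrank_by_median(expr[g, ], surv, percentile = config$percentile)
        }, numeric(1L))
        out$logrank_p <- as.list(pvals)
        out$sig_sa <- prognostic_significance(pvals)
      } else {
        out$skipped_sig_sa <- "no survival file supplied"
      }
      jsonlite::write_json(out, file.path(config$out_dir, "key_genes.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    })
  } else {
    manifest$stages[["keygenes"]] <-
      list(skipped = "GMT and PPI files are both required for key-gene ranking")
  }

  manifest$stages$preprocess$expr <- NULL
  manifest$stages$cluster$fit <- NULL
  manifest$stages$evaluate$enrichment <- NULL
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
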