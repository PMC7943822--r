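# Synthetic data with planted structure: latent-factor co-expression
# modules, two-group differential expression, module-aligned annotation
# terms, expression-linked survival and a hub-and-spoke PPI graph. Every
# generator is a pure function of its specification and seed, so planted
# truth serves as an exact recovery oracle downstream.

#' Simulation specification
#'
#' Defaults describe the package's standard "small" study condition:
#' 5 latent-factor modules of 20 genes plus 100 background genes, 30 tumor
#' and 30 normal samples, within-module correlation 0.8 on the latent scale,
#' and a per-gene differential-expression shift of 2 latent-scale standard
#' deviations carried by every module gene.
#'
#' @param n_modules number of planted modules.
#' @param genes_per_module genes in each module.
#' @param n_background_genes unstructured noise genes.
#' @param n_tumor,n_normal samples per group.
#' @param within_module_corr target pairwise correlation inside a module on
#'   the latent (log) scale, in (0, 1).
#' @param de_effect_size group-mean shift (latent-scale standard deviations)
#'   added to every module gene; modules alternate shift direction so both
#'   up- and down-regulated modules exist. 0 disables differential
#'   expression.
#' @param noise_sd scale of the idiosyncratic gene noise (1 keeps the latent
#'   variance decomposition exact).
#' @param survival_hazard_ratio hazard ratio per unit of the module-1 latent
#'   factor.
#' @param censoring_rate approximate fraction of censored samples in
#'   \[0, 1).
#' @param seed integer seed (mandatory; every generator derives its stream
#'   from it).
#' @return `simulation_spec` list.
#' @export
simulation_spec <- function(n_modules = 5L, genes_per_module = 20L,
                            n_background_genes = 100L,
                            n_tumor = 30L, n_normal = 30L,
                            within_module_corr = 0.8,
                            de_effect_size = 2,
                            noise_sd = 1,
                            survival_hazard_ratio = 3,
                            censoring_rate = 0.2,
                            seed = .default_seed) {
  stopifnot(n_modules >= 0L, genes_per_module >= 0L, n_background_genes >= 0L,
            n_tumor >= 0L, n_normal >= 0L,
            within_module_corr > 0, within_module_corr < 1,
            noise_sd >= 0, censoring_rate >= 0, censoring_rate < 1,
            survival_hazard_ratio > 0)
  structure(list(n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 n_background_genes = as.integer(n_background_genes),
                 n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 within_module_corr = within_module_corr,
                 de_effect_size = de_effect_size,
                 noise_sd = noise_sd,
                 survival_hazard_ratio = survival_hazard_ratio,
                 censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# FPKM-like scale: exponentiate a damped latent signal. The 0.75 damping
# keeps pairwise correlations close to their latent targets after the
# log-normal transform; the +2 offset centers typical expression near
# exp(2) ~ 7 FPKM.
.to_fpkm <- function(z) exp(0.75 * z + 2)

#' Simulate a modular expression matrix with planted truth
#'
#' Per module, a per-sample latent factor is drawn N(0, 1); each module gene
#' is `sqrt(rho) * factor + sqrt(1 - rho) * noise_sd * N(0, 1)` plus a
#' group-indicator shift of `de_effect_size` (direction alternating by
#' module). Background genes are independent noise. The latent signal is
#' then mapped to a non-negative FPKM-like scale by a damped exponential
#' (log-normal expression analogy), so the preprocessing filters operate on
#' realistic magnitudes.
#'
#' @param spec [simulation_spec()].
#' @return list with `expr` (expression matrix), `groups` (sample groups)
#'   and `truth` (`synthetic_truth`: planted labels, latent factors, DE gene
#'   list, module shift signs).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  m <- spec$n_tumor + spec$n_normal
  if (m < 2L) stop("at least 2 samples are required")
  sample_ids <- sprintf("S%03d", seq_len(m))
  groups <- sample_groups(setNames(
    c(rep("tumor", spec$n_tumor), rep("normal", spec$n_normal)), sample_ids))
  x <- as.numeric(groups == "tumor")

  n_mod_genes <- spec$n_modules * spec$genes_per_module
  gene_ids <- c(
    if (n_mod_genes) sprintf("M%02dG%03d",
                             rep(seq_len(spec$n_modules),
                                 each = spec$genes_per_module),
                             seq_len(n_mod_genes)) else character(0L),
    if (spec$n_background_genes) sprintf("BG%04d",
                                         seq_len(spec$n_background_genes))
    else character(0L))

  factors <- if (spec$n_modules) {
    matrix(rnorm(m * spec$n_modules), nrow = m,
           dimnames = list(sample_ids, sprintf("F%02d", seq_len(spec$n_modules))))
  } else matrix(0, nrow = m, ncol = 0L)
  shift_sign <- if (spec$n_modules) (-1)^(seq_len(spec$n_modules) + 1L)
                else integer(0L)

  rho <- spec$within_module_corr
  z <- matrix(0, nrow = length(gene_ids), ncol = m,
              dimnames = list(gene_ids, sample_ids))
  row <- 0L
  for (k in seq_len(spec$n_modules)) {
    for (j in seq_len(spec$genes_per_module)) {
      row <- row + 1L
      z[row, ] <- sqrt(rho) * factors[, k] +
        sqrt(1 - rho) * spec$noise_sd * rnorm(m) +
        spec$de_effect_size * shift_sign[k] * x
    }
  }
  if (spec$n_background_genes) {
    z[(n_mod_genes + 1L):length(gene_ids), ] <-
      matrix(rnorm(spec$n_background_genes * m), ncol = m)
  }
  expr <- .to_fpkm(z)
  validate_expression_matrix(expr)

  labels <- c(rep(seq_len(spec$n_modules), each = spec$genes_per_module),
              rep(NA_integer_, spec$n_background_genes))
  truth <- structure(list(
    module_labels = setNames(labels, gene_ids),
    factors = factors,
    de_genes = if (spec$de_effect_size != 0 && n_mod_genes)
      gene_ids[seq_len(n_mod_genes)] else character(0L),
    shift_sign = shift_sign,
    spec = spec
  ), class = "synthetic_truth")
  list(expr = expr, groups = groups, truth = truth)
}

#' Simulate annotation sets aligned with the planted modules
#'
#' Each planted module yields `terms_per_module` terms containing its genes
#' plus `noise_genes_per_term` random off-module genes; `n_decoy_terms`
#' decoy terms of random genes are appended.
#'
#' @param truth `synthetic_truth` from [simulate_expression()].
#' @param terms_per_module planted terms per module (default 1).
#' @param noise_genes_per_term off-module genes mixed into each planted term
#'   (default 2).
#' @param n_decoy_terms random decoy terms (default 5).
#' @param decoy_size genes per decoy term (default 10).
#' @param seed integer seed.
#' @return [annotation_sets()] object.
#' @export
simulate_annotations <- function(truth, terms_per_module = 1L,
                                 noise_genes_per_term = 2L,
                                 n_decoy_terms = 5L, decoy_size = 10L,
                                 seed = .default_seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  all_genes <- names(truth$module_labels)
  mods <- sort(unique(truth$module_labels[!is.na(truth$module_labels)]))
  sets <- list(); desc <- character(0L)
  for (k in mods) {
    members <- all_genes[!is.na(truth$module_labels) & truth$module_labels == k]
    off <- setdiff(all_genes, members)
    for (t in seq_len(terms_per_module)) {
      id <- sprintf("PLANTED_M%02d_T%d", k, t)
      noise <- if (noise_genes_per_term > 0L && length(off))
        sample(off, min(noise_genes_per_term, length(off))) else character(0L)
      sets[[id]] <- unique(c(members, noise))
      desc[id] <- sprintf("planted term for module %d", k)
    }
  }
  for (d in seq_len(n_decoy_terms)) {
    id <- sprintf("DECOY_T%d", d)
    sets[[id]] <- sample(all_genes, min(decoy_size, length(all_genes)))
    desc[id] <- "decoy term"
  }
  annotation_sets(sets, desc)
}

#' Simulate survival linked to the module-1 latent factor
#'
#' Event times are exponential with per-sample hazard
#' `lambda0 * HR^(factor_1)`, so expression of module-1 genes carries
#' prognostic signal. Censoring times are independent exponentials with the
#' rate tuned so the expected censored fraction approximates
#' `censoring_rate`; at rate 0 every sample is an event.
#'
#' @param truth `synthetic_truth` from [simulate_expression()].
#' @param spec the [simulation_spec()] used for the expression draw.
#' @param base_hazard baseline event rate per time unit (default 0.1).
#' @return survival table (see [survival_table()]).
#' @export
simulate_survival <- function(truth, spec = truth$spec, base_hazard = 0.1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(spec$seed + 1000L)
  sample_ids <- rownames(truth$factors)
  n <- length(sample_ids)
  eta <- if (ncol(truth$factors)) log(spec$survival_hazard_ratio) *
    truth$factors[, 1L] else rep(0, n)
  t_event <- rexp(n, rate = base_hazard * exp(eta))
  if (spec$censoring_rate > 0) {
    lam_c <- base_hazard * spec$censoring_rate / (1 - spec$censoring_rate)
    t_cens <- rexp(n, rate = lam_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  survival_table(sample_ids, pmin(t_event, t_cens),
                 as.integer(t_event <= t_cens))
}

#' Simulate a hub-and-spoke PPI network over the planted modules
#'
#' Each module contributes one planted hub (its first gene) connected to
#' `hub_degree` other members, on top of sparse Erdos-Renyi background
#' edges over all genes.
#'
#' @param truth `synthetic_truth` from [simulate_expression()].
#' @param hub_degree spokes per planted hub (default 8).
#' @param background_edge_p background edge probability (default 0.05).
#' @param seed integer seed.
#' @return list with `ppi` (undirected [igraph::graph]) and `hubs` (named
#'   by module).
#' @export
simulate_ppi <- function(truth, hub_degree = 8L, background_edge_p = 0.05,
                         seed = .default_seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  all_genes <- names(truth$module_labels)
  mods <- sort(unique(truth$module_labels[!is.na(truth$module_labels)]))
  from <- character(0L); to <- character(0L)
  hubs <- character(0L)
  for (k in mods) {
    members <- all_genes[!is.na(truth$module_labels) & truth$module_labels == k]
    hub <- members[1L]
    hubs[as.character(k)] <- hub
    spokes <- sample(setdiff(members, hub),
                     min(hub_degree, length(members) - 1L))
    from <- c(from, rep(hub, length(spokes)))
    to <- c(to, spokes)
  }
  if (background_edge_p > 0 && length(all_genes) >= 2L) {
    pairs <- t(utils::combn(all_genes, 2L))
    pick <- runif(nrow(pairs)) < background_edge_p
    from <- c(from, pairs[pick, 1L])
    to <- c(to, pairs[pick, 2L])
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_genes), name = all_genes)
  if (length(from)) {
    key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
    keep <- !duplicated(key) & from != to
    g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
  }
  list(ppi = g, hubs = hubs)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates expression, groups, annotations, survival and PPI files plus a
#' truth JSON, using the standard readers' formats.
#'
#' @param spec [simulation_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(spec)
  ann <- simulate_annotations(sim$truth, seed = spec$seed + 1L)
  surv <- simulate_survival(sim$truth, spec)
  ppi <- simulate_ppi(sim$truth, seed = spec$seed + 2L)

  paths <- c(expression = file.path(dir, "expression.tsv"),
             groups = file.path(dir, "groups.tsv"),
             gmt = file.path(dir, "annotations.gmt"),
             survival = file.path(dir, "survival.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expr, paths[["expression"]])
  write.table(data.frame(sample_id = names(sim$groups),
                         group = as.character(sim$groups)),
              paths[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(vapply(names(ann), function(term) {
    paste(c(term, attr(ann, "descriptions")[[term]], ann[[term]]),
          collapse = "\t")
  }, character(1L)), paths[["gmt"]])
  write.table(surv, paths[["survival"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  el <- igraph::as_edgelist(ppi$ppi)
  write.table(data.frame(gene1 = el[, 1L], gene2 = el[, 2L]),
              paths[["ppi"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    module_labels = as.list(sim$truth$module_labels),
    de_genes = sim$truth$de_genes,
    hubs = as.list(ppi$hubs),
    spec = unclass(spec)
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA, null = "null")
  paths
}
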