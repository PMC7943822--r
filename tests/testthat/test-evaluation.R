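# two orthogonal rank-1 modules over shared samples
orthogonal_modules <- function(n_per = 5, n_samples = 16, seed = 51) {
  set.seed(seed)
  f1 <- scale(rnorm(n_samples))[, 1]
  f2 <- scale(residuals(lm(rnorm(n_samples) ~ f1)))[, 1]
  expr <- rbind(
    t(vapply(seq_len(n_per), function(i) f1 * runif(1, 0.5, 2), f1)),
    t(vapply(seq_len(n_per), function(i) f2 * runif(1, 0.5, 2), f2)))
  dimnames(expr) <- list(paste0("g", seq_len(2 * n_per)),
                         paste0("s", seq_len(n_samples)))
  labels <- setNames(rep(1:2, each = n_per), rownames(expr))
  list(expr = expr, labels = labels)
}

test_that("error rate is zero for clean modules and flags planted mislabels", {
  om <- orthogonal_modules()
  p <- module_partition(om$labels)
  rep0 <- error_rate(p, om$expr)
  expect_equal(rep0$error_rate, 0)
  expect_true(all(rep0$mm > 0.99))

  wrong <- om$labels
  wrong[["g1"]] <- 2L  # move a module-1 gene into module 2
  rep1 <- error_rate(module_partition(wrong), om$expr)
  expect_true(rep1$violated[["g1"]])
  expect_equal(rep1$error_rate, 1 / length(wrong))
  # direct correlation check of the flag
  me <- update_centers(om$expr, wrong, min_module_size = 1L)$centers
  expect_gt(abs(cor(om$expr["g1", ], me[1, ])),
            abs(cor(om$expr["g1", ], me[2, ])))

  expect_warning(single <- error_rate(
    module_partition(setNames(rep(1L, 10), rownames(om$expr))), om$expr),
    "vacuity")
  expect_equal(single$error_rate, 0)
})

test_that("error rate is invariant to relabeling and gene order", {
  sim <- simulate_expression(simulation_spec(n_modules = 3L,
                                             genes_per_module = 8L,
                                             n_background_genes = 10L,
                                             seed = 13L))
  fit <- run_gcna_kpca(sim$expr)
  base <- error_rate(fit$partition, sim$expr)$error_rate
  # swap module ids 1 and 2
  relab <- setNames(ifelse(fit$partition$labels == 1L, 2L,
                           ifelse(fit$partition$labels == 2L, 1L,
                                  fit$partition$labels)),
                    names(fit$partition$labels))
  p2 <- module_partition(relab)
  shuffled <- sim$expr[sample(nrow(sim$expr)), ]
  expect_equal(error_rate(p2, shuffled)$error_rate, base)
})

test_that("Fisher enrichment equals the hypergeometric tail sum", {
  bg <- paste0("g", 1:100)
  sets <- annotation_sets(list(ALL = bg, T10 = bg[1:10]))
  module <- bg[c(1:5, 50:54)]
  res <- fisher_enrichment(module, sets, bg)
  expect_equal(res$p[res$term == "ALL"], 1)  # term covering all of background
  # overlap 5, term 10, background 100, module 10: P(X >= 5) by direct sum
  oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(res$p[res$term == "T10"], oracle, tolerance = 1e-12)

  none <- fisher_enrichment(bg[60:70], annotation_sets(list(T5 = bg[1:5])), bg)
  expect_equal(none$p, 1)
  expect_error(fisher_enrichment(c("absent"), sets, bg), "absent")
  expect_error(fisher_enrichment(module, sets, character(0)), "background")
})

test_that("enrichment p-values agree with fisher.test across configurations", {
  for (n_bg in c(12L, 25L, 60L)) {
    bg <- paste0("g", seq_len(n_bg))
    for (term_size in c(2L, 5L, n_bg %/% 2L)) {
      for (mod_size in c(3L, n_bg %/% 3L)) {
        sets <- annotation_sets(list(T = bg[seq_len(term_size)]))
        for (ov in 0:min(term_size, mod_size)) {
          module <- c(bg[seq_len(ov)],
                      bg[setdiff(seq_len(n_bg), seq_len(term_size))][
                        seq_len(mod_size - ov)])
          if (anyNA(module)) next
          p_pkg <- fisher_enrichment(module, sets, bg)$p
          tab <- matrix(c(ov, term_size - ov, mod_size - ov,
                          n_bg - term_size - (mod_size - ov)), 2)
          p_or <- fisher.test(tab, alternative = "greater")$p.value
          if (ov == 0) expect_equal(p_pkg, 1) else
            expect_equal(p_pkg, p_or, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("biological significance arithmetic follows the stated sums", {
  expect_equal(gcnakpca:::.sig_from_pvalues(c(0.01, 0.001)), 5)
  expect_equal(gcnakpca:::.sig_from_pvalues(c(0.01, 0.5, 0.001)), 5)
  expect_equal(gcnakpca:::.sig_from_pvalues(c(0.5, 0.9)), 0)
  expect_equal(gcnakpca:::.sig_from_pvalues(0), 300)  # clipped at 1e-300

  # overall Sig is the plain mean of per-module Sig_i, zero modules included
  bg <- paste0("g", 1:40)
  p <- module_partition(setNames(rep(1:2, each = 20), bg))
  sets <- annotation_sets(list(M1 = bg[1:20], DECOY = bg[c(1, 21)]))
  enr <- biological_significance(p, sets, background = bg)
  expect_equal(enr$sig, mean(enr$sig_i))
  expect_gt(enr$sig_i[[1]], 0)
  expect_equal(enr$sig_i[[2]], 0)
})

test_that("planted partitions out-enrich permuted ones on planted terms", {
  better <- 0L
  for (seed in 1:50) {
    sim <- simulate_expression(simulation_spec(n_modules = 3L,
                                               genes_per_module = 10L,
                                               n_background_genes = 20L,
                                               seed = seed))
    truth <- sim$truth$module_labels
    genes <- names(truth)[!is.na(truth)]
    sets <- simulate_annotations(sim$truth, n_decoy_terms = 0L, seed = seed)
    planted <- module_partition(setNames(truth[genes], genes))
    set.seed(seed + 500L)
    perm <- module_partition(setNames(sample(truth[genes]), genes))
    sig_p <- biological_significance(planted, sets, background = genes)$sig
    sig_q <- biological_significance(perm, sets, background = genes)$sig
    if (sig_p > sig_q) better <- better + 1L
  }
  expect_gte(better / 50, 0.95)
})

test_that("logrank p-values match the O-E/variance construction", {
  # mirrored strata: identical curves, statistic 0
  st <- survival_table(paste0("s", 1:8), rep(c(1, 2, 3, 4), 2), rep(1, 8))
  gene <- setNames(c(rep(0, 4), rep(10, 4)), paste0("s", 1:8))
  expect_equal(logrank_by_median(gene, st), 1, tolerance = 1e-12)

  # clearly separated event times
  st2 <- survival_table(paste0("s", 1:6), c(1, 2, 3, 10, 11, 12), rep(1, 6))
  gene2 <- setNames(c(10, 11, 12, 1, 2, 3), paste0("s", 1:6))
  p_pkg <- logrank_by_median(gene2, st2)
  p_or <- logrank_direct(st2$time, st2$event, gene2 > median(gene2))
  expect_equal(p_pkg, p_or, tolerance = 1e-10)
  expect_lt(p_pkg, 0.05)

  # all censored and one-stratum degenerate cases
  st3 <- survival_table(paste0("s", 1:8), 1:8, rep(0, 8))
  expect_equal(logrank_by_median(gene, st3), 1)
  flatgene <- setNames(rep(2, 8), paste0("s", 1:8))
  expect_warning(p_flat <- logrank_by_median(flatgene, st), "one expression stratum")
  expect_equal(p_flat, 1)
})

test_that("random logrank inputs agree with the direct formula", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30L
    ids <- paste0("s", 1:n)
    st <- survival_table(ids, round(rexp(n, 0.2), 2), rbinom(n, 1, 0.7))
    gene <- setNames(rnorm(n), ids)
    if (sum(st$event) == 0) next
    p_pkg <- logrank_by_median(gene, st)
    p_or <- logrank_direct(st$time, st$event,
                           gene > quantile(gene, 0.5, names = FALSE))
    expect_equal(p_pkg, p_or, tolerance = 1e-8)
  }
})

test_that("prognostic significance reproduces the hand-computable sums", {
  expect_equal(round(prognostic_significance(rep(0.05, 10)), 4), 13.0103)
  expect_equal(prognostic_significance(1), 0)
  expect_equal(prognostic_significance(c(0.01, 0.1)), 3)
})

test_that("AUC equals exhaustive pair counting with midrank ties", {
  ids <- paste0("s", 1:8)
  groups <- sample_groups(setNames(rep(c("tumor", "normal"), each = 4), ids))
  sep <- setNames(c(5, 6, 7, 8, 1, 2, 3, 4), ids)
  expect_equal(gene_auc(sep, groups), 1)
  tied <- setNames(rep(3, 8), ids)
  expect_equal(gene_auc(tied, groups), 0.5)
  for (seed in 1:10) {
    set.seed(seed)
    v <- setNames(sample(1:5, 8, replace = TRUE), ids)  # forces ties
    expect_equal(gene_auc(v, groups),
                 auc_pairs(v, groups[ids] == "tumor"), tolerance = 1e-12)
  }
  one_class <- sample_groups(setNames(rep("tumor", 8), ids))
  expect_error(gene_auc(sep, one_class), "both")
})
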