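test_that("eigengene computation covers rank-1, singleton and mixed-sign modules", {
  set.seed(31)
  v <- rnorm(12)
  ident <- matrix(rep(v, each = 5), 5, byrow = FALSE,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  me <- compute_eigengene(ident)
  expect_equal(abs(cor(me, v)), 1, tolerance = 1e-10)
  expect_equal(sum(me^2), 1, tolerance = 1e-12)

  single <- ident[1, , drop = FALSE]
  me1 <- compute_eigengene(single)
  z <- (v - mean(v)) / sd(v)
  expect_equal(abs(cor(me1, z)), 1, tolerance = 1e-12)
  expect_equal(sum(me1^2), 1, tolerance = 1e-12)

  # half g, half -g: rank-1 with balanced loadings; deterministic orientation
  mixed <- rbind(g1 = v, g2 = v, g3 = -v, g4 = -v)
  colnames(mixed) <- paste0("s", 1:12)
  me_m <- compute_eigengene(mixed)
  expect_equal(abs(cor(me_m, v)), 1, tolerance = 1e-10)
  expect_identical(me_m, compute_eigengene(mixed))
  # SVD oracle: the first right singular vector of the standardized matrix
  zs <- t(apply(mixed, 1, function(r) (r - mean(r)) / sd(r)))
  sv <- svd(zs)$v[, 1]
  expect_equal(abs(cor(me_m, sv)), 1, tolerance = 1e-10)

  flat <- rbind(g1 = v, flatg = rep(1, 12))
  colnames(flat) <- paste0("s", 1:12)
  expect_error(compute_eigengene(flat), "flatg")
})

test_that("correlation distance uses the absolute correlation", {
  set.seed(32)
  g <- rnorm(20)
  expect_equal(correlation_distance(g, g), 0, tolerance = 1e-12)
  expect_equal(correlation_distance(g, -g), 0, tolerance = 1e-12)
  # construct a center with correlation exactly 0.65
  gz <- scale(g)[, 1]
  orth <- scale(residuals(lm(rnorm(20) ~ gz)))[, 1]
  center <- 0.65 * gz + sqrt(1 - 0.65^2) * orth
  expect_equal(correlation_distance(g, center), 0.35, tolerance = 1e-10)
  expect_error(correlation_distance(g, rep(1, 20)), "constant")
})

test_that("assignment picks the nearest center with low-index tie-breaks", {
  set.seed(33)
  centers <- t(vapply(1:3, function(i) {
    x <- rnorm(10); x / sqrt(sum(x^2))
  }, numeric(10)))
  colnames(centers) <- paste0("s", 1:10)
  expr <- rbind(gene_c2 = centers[2, ] * 5 + 3)
  colnames(expr) <- paste0("s", 1:10)
  expect_equal(unname(assign_genes(expr, centers)), 2L)
  # exact tie between centers 1 and 2 resolves to 1
  tie_centers <- rbind(centers[1, ], centers[1, ], centers[3, ])
  colnames(tie_centers) <- paste0("s", 1:10)
  g1 <- rbind(g = centers[1, ])
  colnames(g1) <- paste0("s", 1:10)
  expect_equal(unname(assign_genes(g1, tie_centers)), 1L)
  expect_true(all(assign_genes(rand_expr(5, 10, seed = 2),
                               centers[1, , drop = FALSE]) == 1L))
})

test_that("center updates track planted factors and drop dead clusters", {
  set.seed(34)
  f1 <- rnorm(40); f2 <- rnorm(40)
  expr <- rbind(
    t(vapply(1:10, function(i) f1 + rnorm(40, sd = 0.1), numeric(40))),
    t(vapply(1:10, function(i) f2 + rnorm(40, sd = 0.1), numeric(40))))
  dimnames(expr) <- list(paste0("g", 1:20), paste0("s", 1:40))
  labels <- setNames(rep(1:2, each = 10), rownames(expr))
  upd <- update_centers(expr, labels)
  expect_gte(abs(cor(upd$centers[1, ], f1)), 0.99)
  expect_gte(abs(cor(upd$centers[2, ], f2)), 0.99)

  # an undersized cluster is dropped and labels renumbered
  labels2 <- labels
  labels2[1:19] <- 1L; labels2[20] <- 2L
  upd2 <- update_centers(expr, labels2, min_module_size = 3L)
  expect_equal(nrow(upd2$centers), 1L)
  expect_equal(upd2$dropped, 2L)
  expect_equal(unname(upd2$label_map["1"]), 1L)

  # identical member genes reproduce the member profile up to sign/scale
  ident <- expr[rep(1, 4), ]
  rownames(ident) <- paste0("r", 1:4)
  upd3 <- update_centers(ident, setNames(rep(1L, 4), rownames(ident)),
                         min_module_size = 2L)
  expect_equal(abs(cor(upd3$centers[1, ], expr[1, ])), 1, tolerance = 1e-10)
})

test_that("the refinement loop reaches a verified fixpoint deterministically", {
  spec <- simulation_spec(seed = 5L)
  sim <- simulate_expression(spec)
  fit <- run_gcna_kpca(sim$expr)
  expect_true(fit$trace$converged)
  expect_equal(fit$trace$changes[fit$trace$n_iter], 0L)
  # one further assignment pass changes nothing
  relabel <- assign_genes(sim$expr, fit$partition$eigengenes)
  expect_identical(relabel, fit$partition$labels)
  # every gene's label minimizes the correlation distance, checked directly
  for (gene in rownames(sim$expr)) {
    d <- vapply(seq_len(fit$partition$K), function(k) {
      correlation_distance(sim$expr[gene, ], fit$partition$eigengenes[k, ])
    }, numeric(1))
    expect_equal(d[fit$partition$labels[[gene]]], min(d), tolerance = 1e-12)
  }
  # bitwise determinism under an identical seed/config
  fit2 <- run_gcna_kpca(sim$expr)
  expect_identical(fit2$partition$labels, fit$partition$labels)
})

test_that("loop contracts: max_iter cap and edgeless-network error", {
  spec <- simulation_spec(seed = 6L)
  sim <- simulate_expression(spec)
  fit <- run_gcna_kpca(sim$expr, config = kpca_config(max_iter = 1L))
  expect_equal(fit$trace$n_iter, 1L)
  expect_identical(fit$trace$converged, fit$trace$changes[1L] == 0L)
  expect_error(run_gcna_kpca(sim$expr, threshold = 1.01),
               "lower the correlation threshold")
})

test_that("refinement does not worsen the seed partition's error rate", {
  wins <- 0L
  for (seed in 1:15) {
    sim <- simulate_expression(simulation_spec(seed = seed))
    fit <- run_gcna_kpca(sim$expr)
    er_fit <- error_rate(fit$partition, sim$expr)$error_rate
    er_seed <- error_rate(fit$seed_partition, sim$expr)$error_rate
    if (er_fit <= er_seed) wins <- wins + 1L
  }
  expect_gte(wins / 15, 0.9)
})
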