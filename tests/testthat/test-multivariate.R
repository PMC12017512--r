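test_that("PLSC satisfies its algebraic invariants", {
  set.seed(51)
  x <- matrix(rnorm(40 * 12), 40)
  y <- matrix(rnorm(40 * 4), 40)
  fit <- plsc(x, y, n_perm = 100, n_boot = 50, seed = 1)
  # singular values descending, saliences unit norm
  expect_false(is.unsorted(rev(fit$s)))
  expect_equal(colSums(fit$u^2), rep(1, 4), tolerance = 1e-10)
  expect_equal(colSums(fit$v^2), rep(1, 4), tolerance = 1e-10)
  # composite scores are exact projections
  expect_equal(fit$lx, fit$x %*% fit$v, tolerance = 1e-10)
  expect_equal(fit$ly, fit$y %*% fit$u, tolerance = 1e-10)
  # energy conservation: sum s^2 equals ||R||_F^2
  r <- crossprod(fit$y, fit$x)
  expect_equal(sum(fit$s^2), sum(r^2), tolerance = 1e-8)
})

test_that("a perfect latent yields unit score correlation and minimal p", {
  set.seed(52)
  # rank-one brain data driven by a single latent score
  s <- rnorm(50)
  x <- outer(s, rnorm(10))
  y <- s
  fit <- plsc(x, y, n_perm = 100, n_boot = 50, seed = 2)
  expect_equal(abs(cor(fit$lx[, 1], fit$ly[, 1])), 1, tolerance = 1e-8)
  expect_equal(fit$perm_p[1], 1 / 101)
})

test_that("cross-validated PLSC recovers strong latents and not null data", {
  set.seed(53)
  n <- 60
  v <- rnorm(20); u <- rnorm(3)
  s <- rnorm(n)
  x <- outer(s, v) + matrix(rnorm(n * 20), n) * 0.05
  y <- outer(s, u) + matrix(rnorm(n * 3), n) * 0.05
  cv <- plsc_cross_validate(x, y, n_iter = 2, n_perm = 50, seed = 1)
  expect_gt(cv$mean_r, 0.95)
  expect_lt(cv$p, 0.05)
  null_r <- vapply(1:5, function(i) {
    plsc_cross_validate(matrix(rnorm(n * 20), n), matrix(rnorm(n * 3), n),
                        n_iter = 2, n_perm = 0, seed = i)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(null_r)), 0.15)
  expect_error(plsc_cross_validate(x[1:20, ], y[1:20, ]), "25")
})

test_that("PLSR identifies a perfectly predictive gene", {
  set.seed(54)
  genes <- matrix(rnorm(100 * 40), 100)
  colnames(genes) <- sprintf("g%02d", 1:40)
  eff <- genes[, 7]
  pr <- plsr_genes(eff, genes, n_boot = 200, seed = 3)
  expect_equal(names(which.max(abs(pr$bootstrap_z))), "g07")
  expect_true("g07" %in% pr$top_positive)
  expect_gt(pr$explained_variance[1], 0.5)
  expect_length(intersect(pr$top_positive, pr$top_negative), 0)
})

test_that("PLSR explains little response variance under independence", {
  # in-sample PLS1 fit under independence grows like p / (n + p), so the
  # null bound is checked in the p << n regime where it is attainable
  set.seed(55)
  ev <- vapply(1:5, function(i) {
    genes <- matrix(rnorm(200 * 30), 200)
    colnames(genes) <- sprintf("g%03d", 1:30)
    plsr_genes(rnorm(200), genes, n_boot = 10, seed = i)$explained_variance[1]
  }, numeric(1))
  expect_lt(mean(ev), 0.2)
  # and in the p > n regime it is mechanically large (overfit), never > 1
  genes <- matrix(rnorm(100 * 300), 100)
  colnames(genes) <- sprintf("g%03d", 1:300)
  ev2 <- plsr_genes(rnorm(100), genes, n_boot = 10, seed = 9)$explained_variance
  expect_true(all(ev2 >= 0 & ev2 <= 1))
})

test_that("PLSR component-1 weights agree with an established implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(56)
  genes <- matrix(rnorm(60 * 25), 60)
  colnames(genes) <- sprintf("g%02d", 1:25)
  eff <- genes[, 1] * 0.5 + rnorm(60)
  pr <- plsr_genes(eff, genes, n_boot = 10, seed = 1)
  ref <- mixOmics::pls(genes, eff, ncomp = 1, mode = "regression",
                       scale = TRUE)
  w_ref <- as.numeric(ref$loadings$X[, 1])
  expect_gt(abs(cor(pr$gene_weights, w_ref)), 0.999)
})

test_that("hypergeometric enrichment equals the closed-form tail sum", {
  background <- sprintf("g%02d", 1:20)
  sets <- list(inlist = background[1:5], other = background[6:15],
               absent = c("x1", "x2"))
  out <- hypergeom_enrichment(background[1:5], sets, background)
  # closed form: P(K >= 5) drawing 5 from 20 with 5 marked
  expect_equal(out$p_hyper[out$set == "inlist"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(out$p_hyper[out$set == "other"], 1)   # zero overlap
  expect_false("absent" %in% out$set)
  expect_equal(out$p_fdr, p.adjust(out$p_hyper, "BH"))
  # partial overlap: 3 of 5 set members in a 5-gene list
  out2 <- hypergeom_enrichment(background[c(1:3, 6:7)], sets, background)
  expect_equal(out2$p_hyper[out2$set == "inlist"],
               sum(dhyper(3:5, 5, 15, 5)), tolerance = 1e-12)
})

test_that("the surrogate-corrected enrichment flags a planted set only", {
  p <- make_parcels(100, 4)
  rough <- simulate_autocorrelated_maps(parcel_distance(p), 0.2, 1,
                                        seed = 99)[, 1]
  tr <- planted_truth(p, gene_effect_map = rough)
  genes <- simulate_gene_matrix(p, tr, n_genes = 120, n_signal_genes = 12,
                                seed = 7)
  sig <- attr(genes, "signal_genes")
  sets <- list(planted = sig,
               random = sprintf("g%04d", 51:70))
  pr <- plsr_genes(rough, genes, n_boot = 100, seed = 1)
  out <- enrichment_with_surrogate_null(
    pr$top_positive, sets, colnames(genes),
    effect_map = rough, genes = genes,
    distance = parcel_distance(p), n_surrogates = 20, n_boot = 20, seed = 2)
  expect_lt(out$p_hyper[out$set == "planted"],
            out$p_hyper[out$set == "random"])
  expect_true(out$significant[out$set == "planted"])
})

test_that("GMT round-trips through the reader", {
  tmp <- tempfile(fileext = ".gmt")
  on.exit(unlink(tmp))
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), tmp)
  sets <- read_gmt(tmp)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, c("g4", "g5"))
})

test_that("morphometric PCA and MSN satisfy their invariants", {
  set.seed(57)
  # rank-1 features: PC1 proportional to the node pattern, full variance
  v <- rnorm(30)
  feats <- outer(v, c(1, -2, 0.5, 3, 1))
  m <- morph_pca_and_msn(feats + matrix(rnorm(150, 0, 1e-8), 30))
  expect_gt(m$explained[1], 0.999)
  expect_gt(abs(cor(m$pc1, v)), 0.999)
  expect_gte(cor(m$pc1, scale(feats[, 1])[, 1]), 0)   # sign convention
  # identical feature vectors correlate at 1 in the MSN
  f2 <- matrix(rnorm(8 * 5), 8)
  f2[2, ] <- f2[1, ]
  m2 <- morph_pca_and_msn(f2)
  z <- scale(f2)
  expect_equal(m2$msn[1, 2], cor(z[1, ], z[2, ]), tolerance = 1e-12)
  expect_equal(diag(m2$msn), rep(0, 8))
  # PC1 matches the eigendecomposition oracle of the feature covariance
  f3 <- matrix(rnorm(40 * 5), 40)
  m3 <- morph_pca_and_msn(f3)
  z3 <- scale(f3)
  eg <- eigen(crossprod(z3) / (40 - 1))
  oracle <- z3 %*% eg$vectors[, 1]
  if (cor(oracle, m3$pc1) < 0) oracle <- -oracle
  expect_equal(m3$pc1, as.numeric(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  # constant feature dropped with warning
  f4 <- cbind(f3[, 1:4], 1)
  expect_warning(morph_pca_and_msn(f4), "constant")
})
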