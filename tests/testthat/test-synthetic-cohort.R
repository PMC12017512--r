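test_that("parcellation is deterministic, unit-norm, and evenly banded", {
  p1 <- make_parcels(100, 4, seed = 1)
  p2 <- make_parcels(100, 4, seed = 1)
  expect_identical(p1, p2)
  norms <- sqrt(p1$x^2 + p1$y^2 + p1$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_identical(p1$node_id, 0:99)
  expect_equal(as.numeric(table(p1$community)), rep(25, 4))

  p8 <- make_parcels(8, 2)
  expect_equal(as.numeric(table(p8$community)), c(4, 4))

  d <- parcel_distance(p1)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= pi + 1e-12))

  expect_error(make_parcels(7, 2), "4")
})

test_that("planted truth standardizes the contrast and validates inputs", {
  p <- make_parcels(40, 4)
  tr <- planted_truth(p)
  expect_lt(abs(mean(tr$contrast_vector)), 1e-12)
  expect_equal(mean(tr$contrast_vector^2), 1, tolerance = 1e-12)
  expect_error(planted_truth(p, autocorr_length = 0), "positive")
})

test_that("a scan is reproducible and carries no age effect when slope is zero", {
  p <- make_parcels(30, 3)
  tr <- planted_truth(p)
  s1 <- simulate_scan(p, tr, age = 9, seed = 7)
  s2 <- simulate_scan(p, tr, age = 9, seed = 7)
  expect_identical(s1, s2)

  tr0 <- planted_truth(p, age_slope = 0,
                       noise = list(profile = 0, gd_jitter = 0))
  # zero noise makes thresholded MPC degenerate; that warning is expected
  a <- suppressWarnings(simulate_scan(p, tr0, age = 6, seed = 1))
  b <- suppressWarnings(simulate_scan(p, tr0, age = 13, seed = 1))
  expect_identical(a$profiles, b$profiles)

  expect_equal(s1$gd, t(s1$gd))
  expect_true(all(s1$gd >= 0) && all(diag(s1$gd) == 0))
  expect_true(all(s1$ts == round(s1$ts)) && all(s1$ts >= 0))
  expect_equal(diag(s1$fc), rep(1, 30))
  expect_true(all(abs(s1$fc) <= 1 + 1e-12))
})

test_that("planted contrast amplitude grows with age (Monte-Carlo)", {
  p <- make_parcels(30, 3)
  tr <- planted_truth(p, age_slope = 0.05)
  amp_at <- function(age, seeds) {
    mean(vapply(seeds, function(s) {
      sc <- simulate_scan(p, tr, age = age, seed = s)
      sd(rowMeans(sc$profiles))   # node-level spread tracks the amplitude
    }, numeric(1)))
  }
  expect_gt(amp_at(13, 1:50), amp_at(7, 1:50))
})

test_that("cohort design obeys scan-count mixing and age increments", {
  des <- simulate_design(n_subjects = 1000, seed = 4)
  counts <- table(table(des$subject_id))
  props <- as.numeric(counts) / 1000
  nominal <- c(159, 83, 39) / 281
  expect_true(all(abs(props - nominal) < 0.05))
  inc <- tapply(des$age, des$subject_id, function(a) diff(sort(a)))
  expect_true(all(unlist(inc) >= 0.5 - 1e-9))
  des2 <- simulate_design(n_subjects = 1000, seed = 5)
  expect_false(identical(des$age, des2$age))
  expect_error(simulate_design(n_subjects = 5), "10")
  expect_error(simulate_design(n_subjects = 20, age_range = c(6, 6.5)),
               "narrow")
})

test_that("cohorts are byte-identical under a fixed seed", {
  p <- make_parcels(16, 4)
  tr <- planted_truth(p)
  c1 <- simulate_cohort(p, tr, n_subjects = 10, seed = 9)
  c2 <- simulate_cohort(p, tr, n_subjects = 10, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(table(c1$phenotypes$subject_id) %in% 1:3))
})

test_that("gene matrix has sound null and exact loading-one limit", {
  p <- make_parcels(100, 4)
  tr <- planted_truth(p)
  m <- mean(vapply(1:5, function(s) {
    g <- simulate_gene_matrix(p, tr, n_genes = 100, n_signal_genes = 0,
                              seed = s)
    mean(abs(cor(g, tr$gene_effect_map)))
  }, numeric(1)))
  expect_lte(m, 0.2)

  g1 <- simulate_gene_matrix(p, tr, n_genes = 10, n_signal_genes = 3,
                             loading = 1, seed = 1)
  eff <- tr$gene_effect_map
  expect_equal(cor(g1[, 1], eff), 1, tolerance = 1e-12)

  g2 <- simulate_gene_matrix(p, tr, n_genes = 10, n_signal_genes = 3, seed = 2)
  g3 <- simulate_gene_matrix(p, tr, n_genes = 10, n_signal_genes = 3, seed = 2)
  expect_identical(g2, g3)
  expect_error(simulate_gene_matrix(p, tr, n_genes = 5, n_signal_genes = 5),
               "smaller")
})

test_that("autocorrelated maps are standardized and spatially smooth", {
  p <- make_parcels(100, 4)
  d <- parcel_distance(p)
  m <- simulate_autocorrelated_maps(d, 0.5, n = 5, seed = 3)
  expect_equal(colMeans(m), rep(0, 5), tolerance = 1e-12)
  expect_equal(colMeans(m^2), rep(1, 5), tolerance = 1e-12)
  # near pairs more similar than far pairs
  near <- d < 0.5 & upper.tri(d)
  far <- d > 2.5 & upper.tri(d)
  gap <- mean(0.5 * (outer(m[, 1], m[, 1], `-`)[far])^2) -
    mean(0.5 * (outer(m[, 1], m[, 1], `-`)[near])^2)
  expect_gt(gap, 0)
})
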