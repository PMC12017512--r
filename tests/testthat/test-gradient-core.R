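test_that("normalized-angle affinity matches the brute-force oracle", {
  set.seed(11)
  profiles <- matrix(runif(10 * 30), 10)
  aff <- normalized_angle_affinity(profiles)
  expect_equal(aff$values, oracle_normalized_angle(profiles),
               tolerance = 1e-12)

  # identical profiles -> 1; orthogonal profiles -> 0.5
  p2 <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 2))
  a2 <- normalized_angle_affinity(p2)$values
  expect_equal(a2[1, 2], 1)
  expect_equal(a2[1, 3], 0.5)

  p3 <- rbind(c(1, 0), c(0, 0))
  expect_error(normalized_angle_affinity(p3), "zero-norm.*2")
})

test_that("multiscale fusion concatenates the three feature rows", {
  sc <- tiny_cohort()$scans[[1]]
  pr <- prepare_features(sc)
  aff <- build_multiscale_affinity(pr$gd, pr$mpc, pr$ts)
  prof <- cbind(pr$gd$values, pr$mpc$values, pr$ts$values)
  expect_equal(aff$values, oracle_normalized_angle(prof), tolerance = 1e-12)
  expect_equal(diag(aff$values), rep(1, nrow(prof)))
})

test_that("diffusion map matches a dense Markov eigendecomposition oracle", {
  set.seed(12)
  for (n in c(30, 40)) {
    w <- random_affinity(n)
    g <- diffusion_map(w, k = 5, alpha = 0.5)
    o <- oracle_diffusion_map(w, k = 5, alpha = 0.5)
    expect_equal(g$eigenvalues, o$values, tolerance = 1e-8)
    unit <- sweep(g$components, 2, sqrt(colSums(g$components^2)), `/`)
    expect_lt(signed_col_diff(unit, o$vectors), 1e-8)
    # explanation ratios: normalized eigenvalues, descending
    expect_equal(g$explanation_ratio,
                 g$eigenvalues / sum(g$eigenvalues), tolerance = 1e-10)
    expect_false(is.unsorted(rev(g$explanation_ratio)))
  }
})

test_that("component 1 separates two dense blocks by sign", {
  n <- 12
  w <- matrix(0.01, n, n)
  blk <- c(rep(1, 6), rep(2, 6))
  w[outer(blk, blk, "==")] <- 0.9
  diag(w) <- 1
  g <- diffusion_map(w, k = 3)
  s <- sign(g$components[, 1])
  expect_true(all(s[1:6] == s[1]) && all(s[7:12] == -s[1]))
})

test_that("disconnected affinity graphs are rejected with component info", {
  z <- matrix(0, 5, 5)
  w <- rbind(cbind(random_affinity(5), z), cbind(z, random_affinity(5)))
  expect_error(diffusion_map(w, k = 2), "disconnected")
})

test_that("alpha defaults to one half", {
  expect_equal(eval(formals(diffusion_map)$alpha), 0.5)
})

test_that("Procrustes alignment recovers orthogonal mixings exactly", {
  set.seed(13)
  comps <- matrix(rnorm(40 * 4), 40)
  ev <- sort(runif(4), decreasing = TRUE)
  src <- gradient_set(comps, ev)

  same <- procrustes_align(src, src)
  expect_equal(same$components, src$components, tolerance = 1e-12)

  flipped <- src
  flipped$components[, 1] <- -flipped$components[, 1]
  back <- procrustes_align(flipped, src)
  expect_equal(back$components, src$components, tolerance = 1e-10)

  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  target <- src
  target$components <- src$components %*% q
  aligned <- procrustes_align(src, target)
  expect_equal(aligned$components, target$components, tolerance = 1e-10)
  expect_equal(aligned$eigenvalues, src$eigenvalues)

  expect_error(procrustes_align(src, gradient_set(comps[, 1:2], ev[1:2])),
               "node count")
})

test_that("age-bin templates reduce to members in degenerate bins", {
  p <- make_parcels(30, 3)
  tr <- planted_truth(p)
  ages <- c(6.5, 8.5, 9.5, 10.5, 11.5, 12.5)
  scans <- lapply(seq_along(ages), function(i) {
    simulate_scan(p, tr, ages[i], scan_id = paste0("s", i), seed = i)
  })
  prepped <- lapply(scans, prepare_features)
  tm <- group_template(prepped, ages, k = 5)
  expect_named(tm$bins, c("6-7", "8", "9", "10", "11", "12-13"))
  # one scan per bin: template equals that scan's gradients up to alignment
  g1 <- diffusion_map(build_multiscale_affinity(
    prepped[[1]]$gd, prepped[[1]]$mpc, prepped[[1]]$ts), k = 5)
  aligned <- procrustes_align(g1, tm$bins[["6-7"]])
  expect_equal(aligned$components, tm$bins[["6-7"]]$components,
               tolerance = 1e-8)
  # identical scans in a bin: the mean is a member
  prepped2 <- prepped[c(1, 1, 2, 3, 4, 5, 6)]
  ages2 <- c(6.5, 6.6, ages[-1])
  tm2 <- group_template(prepped2, ages2, k = 5)
  aligned2 <- procrustes_align(g1, tm2$bins[["6-7"]])
  expect_equal(aligned2$components, tm2$bins[["6-7"]]$components,
               tolerance = 1e-8)
  expect_error(group_template(prepped[1:3], ages[1:3]), "empty age bin")
})

test_that("pipeline output is invariant to sign flips of raw components", {
  co <- tiny_cohort()
  cg <- cohort_gradients(co, k = 6, orient_to = co$truth$contrast_vector)
  g <- cg$gradients[[3]]
  # re-embed scan 3 and force sign flips before alignment
  pp <- cg$prepped[[3]]
  raw <- diffusion_map(build_multiscale_affinity(pp$gd, pp$mpc, pp$ts), k = 6)
  raw$components <- raw$components %*% diag(c(-1, 1, -1, 1, -1, 1))
  bin <- as.character(cg$templates$membership[3])
  re_aligned <- procrustes_align(raw, cg$templates$bins[[bin]])
  expect_equal(re_aligned$components, g$components, tolerance = 1e-8)
})

test_that("aligned principal gradient recovers the planted contrast", {
  co <- tiny_cohort()
  cg <- cohort_gradients(co, orient_to = co$truth$contrast_vector)
  cors <- vapply(cg$gradients, function(g) {
    cor(g$components[, 1], co$truth$contrast_vector)
  }, numeric(1))
  expect_gt(min(abs(cors)), 0.8)
  expect_gt(mean(cors > 0), 0.99)   # orientation makes the sign positive
})

test_that("feature contributions find a perfectly contributing feature", {
  set.seed(14)
  n <- 50
  p <- make_parcels(n, 4)
  d <- parcel_distance(p)
  base <- simulate_autocorrelated_maps(d, 0.4, n = 9, seed = 2)
  ms <- gradient_set(base[, 1:3], c(3, 2, 1))
  feat_a <- gradient_set(cbind(base[, 1], base[, 4:5]), c(3, 2, 1))
  feat_b <- gradient_set(base[, 6:8], c(3, 2, 1))
  feat_c <- gradient_set(cbind(base[, 9], base[, 5:4]), c(3, 2, 1))
  tab <- feature_contribution(ms, list(a = feat_a, b = feat_b, c = feat_c),
                              d, n_components = 1, n_surrogates = 50,
                              seed = 3)
  ra <- tab$partial_r[tab$feature == "a"]
  expect_gt(ra, 0.95)
  expect_lte(tab$p_surrogate[tab$feature == "a"], 0.05)
})
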