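test_that("the FC gradient separates a two-block connectome", {
  n <- 60
  blk <- rep(1:2, each = 30)
  fc <- 0.1 + 0.7 * outer(blk, blk, "==")
  set.seed(41)
  noise <- matrix(rnorm(n * n, 0, 0.02), n)
  fc <- fc + (noise + t(noise)) / 2
  diag(fc) <- 1
  g <- fc_gradient(fc, k = 3)
  s <- sign(g$components[, 1])
  expect_true(all(s[blk == 1] == s[1]) && all(s[blk == 2] == -s[1]))
  expect_equal(eval(formals(fc_gradient)$threshold), 0.10)
})

test_that("identical FC rows receive identical gradient scores", {
  set.seed(42)
  base <- matrix(rnorm(15 * 15), 15)
  fc <- cov2cor(tcrossprod(base) / 15 + diag(15))
  fc[2, ] <- fc[1, ]; fc[, 2] <- fc[, 1]
  fc[1, 2] <- fc[2, 1] <- max(fc[1, -c(1, 2)])
  diag(fc) <- 1
  g <- fc_gradient(fc, k = 3)
  expect_equal(g$components[1, ], g$components[2, ], tolerance = 1e-6)
})

test_that("nodal coupling matches a brute-force rank-correlation oracle", {
  set.seed(43)
  n <- 50
  a <- abs(matrix(rnorm(n * n), n)); a <- (a + t(a)) / 2; diag(a) <- 1
  fc <- matrix(rnorm(n * n), n); fc <- (fc + t(fc)) / 2; diag(fc) <- 1
  rho <- nodal_coupling(a, fc)
  oracle <- vapply(seq_len(n), function(i) {
    cor(rank(a[i, -i]), rank(fc[i, -i]))
  }, numeric(1))
  expect_equal(rho, oracle, tolerance = 1e-12)
  # monotone transform of the profile gives rho 1; reversal gives -1
  fc2 <- a^3
  expect_equal(nodal_coupling(a, fc2)[1], 1)
  expect_equal(nodal_coupling(a, -a)[2], -1)
})

test_that("participation coefficient hits its closed forms exactly", {
  comm <- c("A", "A", "B", "B", "C", "C")
  # node 1: all weight inside community A -> 0
  w1 <- matrix(0, 6, 6)
  w1[1, 2] <- w1[2, 1] <- 3
  expect_equal(participation_coefficient(w1, comm)[1], 0)
  # node 1: equal split between two communities -> 1 - 2 (1/2)^2 = 0.5
  w2 <- matrix(0, 6, 6)
  w2[1, 2] <- w2[2, 1] <- 2
  w2[1, 3] <- w2[3, 1] <- 2
  expect_equal(participation_coefficient(w2, comm)[1], 0.5)
  # node 1: equal split across all three communities -> 1 - 1/3
  w3 <- matrix(0, 6, 6)
  w3[1, 2] <- w3[2, 1] <- 1
  w3[1, 3] <- w3[3, 1] <- 1
  w3[1, 5] <- w3[5, 1] <- 1
  expect_equal(participation_coefficient(w3, comm)[1], 1 - 1 / 3)
  # isolated node gets 0; negative weights are rejected
  expect_equal(participation_coefficient(matrix(0, 3, 3), c("A", "A", "B")),
               rep(0, 3))
  expect_error(participation_coefficient(-w2, comm), "nonnegative")
})

test_that("differentiation distances match a brute-force pair loop", {
  set.seed(44)
  pts <- matrix(rnorm(30), 15)
  comm <- rep(c("A", "B", "C"), each = 5)
  sp <- structure(list(points = pts, centroid = colMeans(pts)),
                  class = "gradient_space_2d")
  out <- differentiation_distance(sp, comm)
  d <- as.matrix(dist(pts))
  for (r in seq_len(nrow(out))) {
    ia <- which(comm == out$community_a[r])
    ib <- which(comm == out$community_b[r])
    vals <- if (out$community_a[r] == out$community_b[r]) {
      d[ia, ib][upper.tri(d[ia, ib])]
    } else as.numeric(d[ia, ib])
    expect_equal(out$mean_distance[r], mean(vals))
  }
  # coincident nodes: all means zero; two point-clusters at distance 5
  same <- structure(list(points = matrix(1, 10, 2), centroid = c(1, 1)),
                    class = "gradient_space_2d")
  expect_true(all(differentiation_distance(same,
                                           rep(c("A", "B"), 5))$mean_distance == 0))
  two <- structure(list(points = rbind(matrix(0, 4, 2),
                                       cbind(rep(5, 4), 0)),
                        centroid = c(2.5, 0)),
                   class = "gradient_space_2d")
  o2 <- differentiation_distance(two, rep(c("A", "B"), each = 4))
  expect_equal(o2$mean_distance[o2$community_a != o2$community_b], 5)
  expect_equal(o2$mean_distance[o2$community_a == o2$community_b], c(0, 0))
})

test_that("coupling aligns with the planted hierarchy where FC tracks structure", {
  co <- tiny_cohort()
  fc_mean <- Reduce(`+`, lapply(co$scans, `[[`, "fc")) / length(co$scans)
  pr <- lapply(co$scans, prepare_features)
  aff <- Reduce(`+`, lapply(pr, function(p) {
    build_multiscale_affinity(p$gd, p$mpc, p$ts)$values
  })) / length(pr)
  rho <- nodal_coupling(aff, fc_mean)
  expect_true(all(is.finite(rho)))
  expect_gt(mean(rho), 0)   # FC is generated as a transform of the affinity
})
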