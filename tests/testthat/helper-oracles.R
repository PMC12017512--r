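# Independent oracles used across the suite.  These deliberately
# re-derive each quantity along a different computational path than the
# package implementation.

# Partial correlation matrix from the 3-variable closed form
# r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
# controlling for the cortex-mean profile.
oracle_partial_cor <- function(profiles) {
  n <- nrow(profiles)
  z <- colMeans(profiles)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rxy <- cor(profiles[i, ], profiles[j, ])
      rxz <- cor(profiles[i, ], z)
      ryz <- cor(profiles[j, ], z)
      out[i, j] <- out[j, i] <-
        (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    }
  }
  out
}

# Brute-force double-loop normalized-angle affinity.
oracle_normalized_angle <- function(profiles) {
  n <- nrow(profiles)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cs <- sum(profiles[i, ] * profiles[j, ]) /
        (sqrt(sum(profiles[i, ]^2)) * sqrt(sum(profiles[j, ]^2)))
      cs <- min(1, max(-1, cs))
      out[i, j] <- 1 - acos(cs) / pi
    }
  }
  out
}

# Dense eigendecomposition of the explicit (non-symmetrized) Markov matrix;
# returns unit-norm right eigenvectors of the nontrivial spectrum.
oracle_diffusion_map <- function(w, k, alpha = 0.5) {
  d <- rowSums(w)
  wa <- w / outer(d^alpha, d^alpha)
  p <- wa / rowSums(wa)
  eg <- eigen(p)
  stopifnot(max(abs(Im(eg$values))) < 1e-10)
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- Re(eg$values)[ord]
  vecs <- Re(eg$vectors)[, ord, drop = FALSE]
  keep <- 2:(k + 1)
  v <- vecs[, keep, drop = FALSE]
  v <- sweep(v, 2, sqrt(colSums(v^2)), `/`)
  list(values = vals[keep], vectors = v)
}

# Align signs of the columns of a to those of b, then return max abs diff.
signed_col_diff <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * b[, j]) < 0) a[, j] <- -a[, j]
  }
  max(abs(a - b))
}

# Random symmetric connected affinity with unit diagonal.
random_affinity <- function(n) {
  a <- matrix(runif(n * n, 0.05, 1), n)
  s <- (a + t(a)) / 2
  diag(s) <- 1
  s
}

# Small cohort shared across tests (built once per test run).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- make_parcels(60, 4)
      tr <- planted_truth(p, age_slope = 0.05)
      cache <<- simulate_cohort(p, tr, n_subjects = 40, seed = 42)
    }
    cache
  }
})
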