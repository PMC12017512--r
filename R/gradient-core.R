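# Core gradient machinery: normalized-angle affinity over the concatenated
# feature profiles, diffusion-map embedding, age-group templates, and
# Procrustes alignment of individual gradients.

#' Normalized-angle affinity from the three prepared features
#'
#' Each node's connectivity profile is the concatenation of its rows in the
#' prepared GD, MPC, and TS matrices (length 3N).  The affinity between two
#' nodes is `1 - arccos(cosine_similarity) / pi`, with the cosine clipped to
#' `[-1, 1]` and the diagonal forced to 1.
#'
#' @param gd,mpc,ts Prepared (`rank_normalize_rescale`d) `feature_matrix`
#'   objects over the same node set.
#' @return An `affinity_matrix` (fields `values`, `kernel`, `source`).
#' @export
build_multiscale_affinity <- function(gd, mpc, ts) {
  vals <- lapply(list(gd, mpc, ts), function(f) {
    if (inherits(f, "feature_matrix")) f$values else as.matrix(f)
  })
  n <- nrow(vals[[1]])
  if (!all(vapply(vals, nrow, 1L) == n)) {
    stop("feature matrices must share the node set", call. = FALSE)
  }
  profiles <- do.call(cbind, vals)
  normalized_angle_affinity(profiles, source = "multiscale")
}

#' Normalized-angle similarity of row profiles
#'
#' @param profiles Node-by-feature profile matrix.
#' @param source Provenance tag (`"multiscale"`, `"fc"`, `"msn"`, ...).
#' @return An `affinity_matrix` with values in `[0, 1]`, diagonal 1.
#' @export
normalized_angle_affinity <- function(profiles, source = "multiscale") {
  norms <- sqrt(rowSums(profiles^2))
  zero <- which(norms < 1e-14)
  if (length(zero)) {
    stop("zero-norm profile at node(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  u <- profiles / norms
  cs <- tcrossprod(u)
  cs[cs > 1] <- 1
  cs[cs < -1] <- -1
  aff <- 1 - acos(cs) / pi
  aff <- (aff + t(aff)) / 2
  diag(aff) <- 1
  structure(list(values = aff, kernel = "normalized_angle", source = source),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity_matrix [%s/%s] %d nodes\n", x$source, x$kernel,
              nrow(x$values)))
  invisible(x)
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Standard diffusion-map construction: the affinity `W` is
#' anisotropy-corrected as `D^-alpha W D^-alpha`, row-normalized to a Markov
#' matrix, and eigendecomposed; the trivial constant eigenvector is dropped
#' and the next `k` right eigenvectors, scaled by `lambda / (1 - lambda)`
#' (the automatic diffusion-time convention), are returned.  Component signs
#' are fixed deterministically (largest-magnitude element positive).
#'
#' @param aff An `affinity_matrix` or plain symmetric nonnegative matrix.
#' @param k Number of components to retain (`k < N`).
#' @param alpha Diffusion anisotropy parameter; 0.5 is the conventional
#'   default for connectome gradients.
#' @return A `gradient_set`: `components` (N x k), `eigenvalues` (raw Markov
#'   eigenvalues, descending), `explanation_ratio`
#'   (eigenvalue / sum of retained eigenvalues), `lambdas` (the
#'   `lambda/(1-lambda)` scales), `alpha`, `alignment_ref`.
#' @export
diffusion_map <- function(aff, k = 10L, alpha = 0.5) {
  w <- if (inherits(aff, "affinity_matrix")) aff$values else as.matrix(aff)
  n <- nrow(w)
  if (k >= n) stop("k must be smaller than the node count", call. = FALSE)
  if (any(w < 0)) stop("affinity must be nonnegative", call. = FALSE)
  comp <- connected_components(w)
  if (max(comp) > 1L) {
    stop("affinity graph is disconnected (", max(comp), " components; sizes ",
         paste(tabulate(comp), collapse = ", "), ")", call. = FALSE)
  }
  d <- rowSums(w)
  wa <- w / outer(d^alpha, d^alpha)
  da <- rowSums(wa)
  # symmetric conjugate of the Markov matrix: same spectrum, real eigenvectors
  s <- wa / outer(sqrt(da), sqrt(da))
  s <- (s + t(s)) / 2
  eg <- eigen(s, symmetric = TRUE)
  psi <- eg$vectors / sqrt(da)           # right eigenvectors of the Markov matrix
  lam <- eg$values
  keep <- 2:(k + 1)
  ev <- lam[keep]
  if (any(ev < 0)) {
    warning("negative eigenvalues among retained components", call. = FALSE)
  }
  scale <- ev / (1 - pmin(ev, 1 - 1e-12))
  comps <- psi[, keep, drop = FALSE] * rep(scale, each = n)
  # deterministic sign: element of largest magnitude positive
  for (j in seq_len(ncol(comps))) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  gradient_set(comps, ev, alpha = alpha)
}

#' Construct a gradient set
#'
#' @param components Node-by-k component matrix.
#' @param eigenvalues Length-k nonnegative, descending.
#' @param alpha Diffusion anisotropy parameter used.
#' @param alignment_ref Identifier of the alignment template, or `NA`.
#' @return A `gradient_set` object.
#' @export
gradient_set <- function(components, eigenvalues, alpha = 0.5,
                         alignment_ref = NA_character_) {
  components <- as.matrix(components)
  if (length(eigenvalues) != ncol(components)) {
    stop("one eigenvalue per component required", call. = FALSE)
  }
  if (is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be in descending order", call. = FALSE)
  }
  structure(list(
    components = components,
    eigenvalues = eigenvalues,
    explanation_ratio = eigenvalues / sum(eigenvalues),
    alpha = alpha,
    alignment_ref = alignment_ref
  ), class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set: %d nodes x %d components (alpha = %g)\n",
              nrow(x$components), ncol(x$components), x$alpha))
  cat("  explanation ratio:",
      paste(sprintf("%.3f", utils::head(x$explanation_ratio, 5)),
            collapse = " "),
      if (ncol(x$components) > 5) "..." else "", "\n")
  invisible(x)
}

#' Procrustes alignment of one gradient set to a target
#'
#' Finds the orthogonal transform (rotation plus reflection, no scaling)
#' minimizing the Frobenius distance between the source components and the
#' target, and applies it.  Eigenvalues and explanation ratios are carried
#' through unchanged.
#'
#' @param source,target `gradient_set` objects with matching dimensions.
#' @param ref Label recorded in `alignment_ref`.
#' @return The aligned `gradient_set`.
#' @export
procrustes_align <- function(source, target, ref = "template") {
  a <- source$components
  b <- if (inherits(target, "gradient_set")) target$components else as.matrix(target)
  if (!all(dim(a) == dim(b))) {
    stop("source and target must share node count and k", call. = FALSE)
  }
  sv <- svd(crossprod(a, b))
  q <- sv$u %*% t(sv$v)
  out <- source
  out$components <- a %*% q
  out$alignment_ref <- ref
  out
}

age_bin_breaks_default <- c(6, 8, 9, 10, 11, 12, 14)

#' Assign scans to age bins
#'
#' Default bins are one-year groups with the extremes pooled:
#' 6-7, 8, 9, 10, 11, 12-13 years.
#'
#' @param ages Numeric vector of ages.
#' @param breaks Bin breaks (right-open; last bin right-closed).
#' @return Factor of bin labels.
#' @export
age_bins <- function(ages, breaks = age_bin_breaks_default) {
  labs <- vapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1] - 1
    if (hi > lo) sprintf("%g-%g", lo, hi) else sprintf("%g", lo)
  }, "")
  cut(ages, breaks = breaks, labels = labs, right = FALSE,
      include.lowest = TRUE)
}

#' Group-level gradient templates by age bin
#'
#' Averages the prepared feature matrices within each age bin (and over all
#' scans), builds the fused affinity of each average, embeds it, and
#' Procrustes-aligns every bin template to the all-scan template.
#'
#' @param prepped List (one per scan) of prepared feature lists as returned
#'   by [prepare_features()].
#' @param ages Ages of the scans, same order.
#' @param breaks Age-bin breaks; see [age_bins()].
#' @param k,alpha Passed to [diffusion_map()].
#' @return List with `overall` (`gradient_set`), `bins` (named list of
#'   aligned `gradient_set`s), and `membership` (bin factor per scan).
#' @export
group_template <- function(prepped, ages, breaks = age_bin_breaks_default,
                           k = 10L, alpha = 0.5) {
  bins <- age_bins(ages, breaks)
  if (anyNA(bins)) stop("ages outside the bin range", call. = FALSE)
  empty <- setdiff(levels(bins), unique(as.character(bins)))
  if (length(empty)) {
    stop("empty age bin(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  mean_feats <- function(idx) {
    lapply(c(gd = "gd", mpc = "mpc", ts = "ts"), function(f) {
      m <- Reduce(`+`, lapply(prepped[idx], function(p) p[[f]]$values)) /
        length(idx)
      structure(list(values = m, kind = toupper(f), mask = m != 0),
                class = "feature_matrix")
    })
  }
  embed <- function(feats) {
    diffusion_map(build_multiscale_affinity(feats$gd, feats$mpc, feats$ts),
                  k = k, alpha = alpha)
  }
  overall <- embed(mean_feats(seq_along(prepped)))
  bin_templates <- lapply(levels(bins), function(b) {
    g <- embed(mean_feats(which(bins == b)))
    procrustes_align(g, overall, ref = "overall")
  })
  names(bin_templates) <- levels(bins)
  list(overall = overall, bins = bin_templates, membership = bins)
}

#' Orient gradient components against a reference map
#'
#' Flips the sign of each requested component so that it correlates
#' positively with the reference vector.  Used to fix the arbitrary global
#' sign so that, e.g., the primary-proxy end of the principal gradient is
#' positive.
#'
#' @param g A `gradient_set`.
#' @param reference Numeric node vector.
#' @param components Indices of components to orient.
#' @return The oriented `gradient_set`.
#' @export
orient_gradients <- function(g, reference, components = 1L) {
  for (j in components) {
    if (stats::cor(g$components[, j], reference) < 0) {
      g$components[, j] <- -g$components[, j]
    }
  }
  g
}

#' Per-scan aligned gradients for a cohort
#'
#' Runs the full individual-gradient pipeline: feature preparation, fused
#' affinity, diffusion-map embedding, and Procrustes alignment of each
#' scan's gradients to its age-bin template (itself aligned to the all-scan
#' template).
#'
#' @param cohort A `synthetic_cohort` (or list with `scans`, `phenotypes`).
#' @param breaks Age-bin breaks.
#' @param k,alpha Embedding parameters.
#' @param orient_to Optional node vector used to orient the overall template
#'   (and hence all aligned gradients) via [orient_gradients()].
#' @return List with `gradients` (named list of aligned `gradient_set`s, one
#'   per scan), `templates` (output of [group_template()]), and `prepped`.
#' @export
cohort_gradients <- function(cohort, breaks = age_bin_breaks_default,
                             k = 10L, alpha = 0.5, orient_to = NULL) {
  scans <- cohort$scans
  prepped <- lapply(scans, prepare_features)
  ages <- vapply(scans, `[[`, 0, "age")
  templates <- group_template(prepped, ages, breaks = breaks, k = k,
                              alpha = alpha)
  if (!is.null(orient_to)) {
    oriented <- orient_gradients(templates$overall, orient_to,
                                 components = seq_len(k))
    flip <- sign(colSums(oriented$components * templates$overall$components))
    templates$overall <- oriented
    templates$bins <- lapply(templates$bins, function(b) {
      b$components <- b$components * rep(flip, each = nrow(b$components))
      b
    })
  }
  grads <- vector("list", length(scans))
  names(grads) <- names(scans)
  for (i in seq_along(scans)) {
    g <- diffusion_map(build_multiscale_affinity(
      prepped[[i]]$gd, prepped[[i]]$mpc, prepped[[i]]$ts), k = k, alpha = alpha)
    bin <- as.character(templates$membership[i])
    grads[[i]] <- procrustes_align(g, templates$bins[[bin]], ref = bin)
  }
  list(gradients = grads, templates = templates, prepped = prepped)
}

#' Feature contributions to the fused gradients
#'
#' For each fused-gradient component and each single-feature gradient
#' component, the partial Pearson correlation controlling for the other two
#' features' corresponding components, with significance from
#' variogram-matched surrogate maps of the fused component.
#'
#' @param multiscale `gradient_set` of the fused connectome.
#' @param per_feature Named list of three `gradient_set`s (single features),
#'   aligned to the same template as `multiscale`.
#' @param distance Node distance matrix for the surrogate model.
#' @param n_components How many components of each set to compare.
#' @param n_surrogates Surrogate maps per test (1,000 for inference).
#' @param seed RNG seed for the surrogates.
#' @return Data frame with columns `ms_component`, `feature`,
#'   `feature_component`, `partial_r`, `p_surrogate`.
#' @export
feature_contribution <- function(multiscale, per_feature, distance,
                                 n_components = 3L, n_surrogates = 1000L,
                                 seed = 1L) {
  stopifnot(length(per_feature) == 3L, !is.null(names(per_feature)))
  feats <- names(per_feature)
  res <- list()
  for (m in seq_len(n_components)) {
    y <- multiscale$components[, m]
    ens <- make_surrogates(y, distance, n = n_surrogates, seed = seed + m)
    for (f in feats) {
      others <- setdiff(feats, f)
      for (cc in seq_len(n_components)) {
        x <- per_feature[[f]]$components[, cc]
        z <- cbind(per_feature[[others[1]]]$components[, cc],
                   per_feature[[others[2]]]$components[, cc])
        r <- partial_cor(y, x, z)
        null_r <- apply(ens$maps, 1, function(s) partial_cor(s, x, z))
        p <- (1 + sum(abs(null_r) >= abs(r))) / (length(null_r) + 1)
        res[[length(res) + 1L]] <- data.frame(
          ms_component = m, feature = f, feature_component = cc,
          partial_r = r, p_surrogate = p, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

#' Partial Pearson correlation of two vectors given covariates
#'
#' @param x,y Numeric vectors.
#' @param z Matrix of control variables (one column each).
#' @return Scalar partial correlation.
#' @export
partial_cor <- function(x, y, z) {
  z <- cbind(1, as.matrix(z))
  q <- qr(z)
  stats::cor(qr.resid(q, x), qr.resid(q, y))
}
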