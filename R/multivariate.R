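# Multivariate brain-behavior and brain-transcriptome inference: partial
# least squares correlation (PLSC) with permutation, bootstrap, and
# cross-validation; single-response partial least squares regression
# (PLSR) with bootstrap Z scores for gene weighting; over-representation
# with a spatial-surrogate null; and morphometric PCA / similarity
# networks.

zscore_cols <- function(m, drop_constant = TRUE) {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd)
  if (drop_constant && any(sds == 0)) {
    warning(sum(sds == 0), " constant column(s) dropped", call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(m, center = TRUE, scale = sds)
}

plsc_svd <- function(x, y) {
  r <- crossprod(y, x)                  # behavior x brain cross-covariance
  sv <- svd(r)
  list(u = sv$u, v = sv$v, s = sv$d, r = r)
}

#' Partial least squares correlation (PLSC)
#'
#' Columns of `X` (brain) and `Y` (behavior) are z-scored, the
#' cross-covariance `R = t(Y) %*% X` is decomposed by SVD
#' (`R = U S t(V)`), and composite scores `Lx = X V`, `Ly = Y U` are
#' formed.  Component significance is a permutation test (rows of `Y`
#' shuffled, singular values compared component-wise); loading stability is
#' assessed by bootstrap resampling of subjects with saliences sign-aligned
#' to the original solution.
#'
#' @param x Subject-by-brain matrix.
#' @param y Subject-by-behavior matrix (or vector).
#' @param n_perm,n_boot Resampling counts (1,000 each for inference).
#' @param seed RNG seed.
#' @return A `plsc_result`: `s` (singular values), `u`, `v` (unit-norm
#'   saliences), `lx`, `ly` (composite scores), `perm_p` (per component),
#'   `brain_loadings`, `behavior_loadings` (correlations of raw columns
#'   with the composites), `boot` (per-loading bootstrap CIs and
#'   `keep` flags for component 1), `x`, `y` (the z-scored data).
#' @export
plsc <- function(x, y, n_perm = 1000L, n_boot = 1000L, seed = 1L) {
  y <- as.matrix(y)
  if (nrow(y) != nrow(as.matrix(x))) stop("subject mismatch", call. = FALSE)
  if (nrow(y) < 10L) stop("need at least 10 subjects", call. = FALSE)
  if (n_perm < 100L) warning("fewer than 100 permutations", call. = FALSE)
  xs <- zscore_cols(x)
  ys <- zscore_cols(y)
  fit <- plsc_svd(xs, ys)
  lx <- xs %*% fit$v
  ly <- ys %*% fit$u
  nc <- length(fit$s)
  set.seed(seed)
  perm_ge <- integer(nc)
  for (p in seq_len(n_perm)) {
    sp <- plsc_svd(xs, ys[sample.int(nrow(ys)), , drop = FALSE])$s
    perm_ge <- perm_ge + (sp >= fit$s)
  }
  perm_p <- (1 + perm_ge) / (n_perm + 1)
  brain_loadings <- stats::cor(xs, lx)
  behavior_loadings <- stats::cor(ys, ly)
  boot_brain <- matrix(NA_real_, n_boot, ncol(xs))
  boot_beh <- matrix(NA_real_, n_boot, ncol(ys))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(xs), replace = TRUE)
    fb <- tryCatch(plsc_svd(zscore_cols(xs[idx, , drop = FALSE]),
                            zscore_cols(ys[idx, , drop = FALSE])),
                   warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fb)) next
    # sign-align component 1 saliences to the original by cosine
    if (sum(fb$v[, 1] * fit$v[, 1]) < 0) {
      fb$v[, 1] <- -fb$v[, 1]; fb$u[, 1] <- -fb$u[, 1]
    }
    lxb <- zscore_cols(xs[idx, , drop = FALSE]) %*% fb$v[, 1]
    lyb <- zscore_cols(ys[idx, , drop = FALSE]) %*% fb$u[, 1]
    boot_brain[b, ] <- stats::cor(xs[idx, , drop = FALSE], lxb)
    boot_beh[b, ] <- stats::cor(ys[idx, , drop = FALSE], lyb)
  }
  ci <- function(m) {
    lo <- apply(m, 2, stats::quantile, 0.025, na.rm = TRUE)
    hi <- apply(m, 2, stats::quantile, 0.975, na.rm = TRUE)
    data.frame(lower = lo, upper = hi, keep = lo > 0 | hi < 0)
  }
  structure(list(
    s = fit$s, u = fit$u, v = fit$v, lx = lx, ly = ly,
    perm_p = perm_p,
    brain_loadings = brain_loadings,
    behavior_loadings = behavior_loadings,
    boot = list(brain = ci(boot_brain), behavior = ci(boot_beh)),
    x = xs, y = ys
  ), class = "plsc_result")
}

#' @export
print.plsc_result <- function(x, ...) {
  cat(sprintf(
    "plsc_result: %d components; s1 = %.3f (perm p = %.4f), cor(Lx1, Ly1) = %.3f\n",
    length(x$s), x$s[1], x$perm_p[1], stats::cor(x$lx[, 1], x$ly[, 1])))
  invisible(x)
}

#' Cross-validated PLSC association
#'
#' Repeated k-fold cross-validation of the first latent component: PLSC is
#' fit on each training split, the held-out subjects are projected with the
#' training saliences, and their composite scores correlated.  Significance
#' comes from permuting the test-set behavior within each fold.
#'
#' @param x,y As in [plsc()].
#' @param n_iter Number of cross-validation repetitions (default 10).
#' @param n_folds Folds per repetition (default 5).
#' @param n_perm Permutations of the test behavior per fold.
#' @param seed RNG seed.
#' @return List: `mean_r` (mean held-out correlation), `fold_r`, `p`
#'   (permutation p for the mean), `null_mean_r`.
#' @export
plsc_cross_validate <- function(x, y, n_iter = 10L, n_folds = 5L,
                                n_perm = 1000L, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 25L) stop("need at least 25 subjects", call. = FALSE)
  set.seed(seed)
  fold_r <- numeric(0)
  null_sum <- NULL
  for (it in seq_len(n_iter)) {
    folds <- sample(rep_len(seq_len(n_folds), n))
    for (f in seq_len(n_folds)) {
      test <- which(folds == f)
      if (length(test) < 3L) stop("fold smaller than 3 subjects", call. = FALSE)
      train <- setdiff(seq_len(n), test)
      xtr <- zscore_cols(x[train, , drop = FALSE])
      ytr <- zscore_cols(y[train, , drop = FALSE])
      fit <- plsc_svd(xtr, ytr)
      ctr <- attr(xtr, "scaled:center"); str_ <- attr(xtr, "scaled:scale")
      cty <- attr(ytr, "scaled:center"); sty <- attr(ytr, "scaled:scale")
      xte <- scale(x[test, , drop = FALSE], ctr, str_)
      yte <- scale(y[test, , drop = FALSE], cty, sty)
      lx <- xte %*% fit$v[, 1]
      ly <- yte %*% fit$u[, 1]
      fold_r <- c(fold_r, stats::cor(lx, ly))
      if (n_perm > 0L) {
        nr <- vapply(seq_len(n_perm), function(...) {
          stats::cor(lx, ly[sample.int(length(ly))])
        }, numeric(1))
        null_sum <- if (is.null(null_sum)) nr else null_sum + nr
      }
    }
  }
  mean_r <- mean(fold_r)
  null_mean <- if (is.null(null_sum)) numeric(0) else
    null_sum / (n_iter * n_folds)
  p <- if (length(null_mean)) {
    (1 + sum(null_mean >= mean_r)) / (length(null_mean) + 1)
  } else NA_real_
  list(mean_r = mean_r, fold_r = fold_r, p = p, null_mean_r = null_mean)
}

# Single-response NIPALS PLS regression on z-scored genes / centered map.
pls1_fit <- function(x, y, n_components) {
  x0 <- x; y0 <- y
  n_components <- min(n_components, ncol(x), nrow(x) - 1L)
  w_list <- t_list <- list()
  expl <- numeric(n_components)
  ssy <- sum(y0^2)
  for (h in seq_len(n_components)) {
    w <- crossprod(x, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { n_components <- h - 1L; break }
    w <- w / nw
    tt <- x %*% w
    tn <- sum(tt^2)
    p <- crossprod(x, tt) / tn
    q <- sum(y * tt) / tn
    expl[h] <- (q^2 * tn) / ssy
    x <- x - tcrossprod(tt, p)
    y <- y - as.numeric(tt) * q
    w_list[[h]] <- as.numeric(w)
    t_list[[h]] <- as.numeric(tt)
  }
  list(weights = w_list, scores = t_list,
       explained = expl[seq_len(n_components)])
}

#' PLSR of a spatial effect map on gene expression
#'
#' Single-response partial least squares regression (NIPALS) of a per-node
#' effect map on a region-by-gene expression matrix.  The first component's
#' gene weights are turned into bootstrap Z scores (weight divided by its
#' standard deviation over region resampling, sign-aligned per resample)
#' and the top 10% positive- and negative-Z genes are selected.
#'
#' @param effect_map Numeric node vector (e.g., a signed age-effect map).
#' @param genes Region-by-gene matrix with gene names in columns.
#' @param n_components Components to extract (default 10).
#' @param n_boot Bootstrap resamples (1,000 for inference).
#' @param top_fraction Fraction of genes in each top list (default 0.10).
#' @param seed RNG seed.
#' @return A `plsr_result`: `explained_variance` (of the response, per
#'   component), `scores` (region scores, component 1), `gene_weights`,
#'   `bootstrap_z`, `top_positive`, `top_negative`.
#' @export
plsr_genes <- function(effect_map, genes, n_components = 10L, n_boot = 1000L,
                       top_fraction = 0.10, seed = 1L) {
  genes <- as.matrix(genes)
  if (length(effect_map) != nrow(genes)) stop("region mismatch", call. = FALSE)
  if (nrow(genes) < 20L) warning("fewer than 20 regions; unstable", call. = FALSE)
  xs <- zscore_cols(genes)
  y <- effect_map - mean(effect_map)
  fit <- pls1_fit(xs, y, n_components)
  w1 <- fit$weights[[1]]
  set.seed(seed)
  boot_w <- matrix(NA_real_, n_boot, length(w1))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(xs), replace = TRUE)
    yb <- y[idx]
    wb <- crossprod(xs[idx, , drop = FALSE], yb - mean(yb))
    nw <- sqrt(sum(wb^2))
    if (nw < 1e-300) next
    wb <- as.numeric(wb) / nw
    if (sum(wb * w1) < 0) wb <- -wb
    boot_w[b, ] <- wb
  }
  sdw <- apply(boot_w, 2, stats::sd, na.rm = TRUE)
  z <- w1 / ifelse(sdw > 0, sdw, Inf)
  names(z) <- colnames(genes)
  n_top <- max(1L, round(top_fraction * length(z)))
  ord <- order(z, decreasing = TRUE)
  top_pos <- names(z)[ord[seq_len(n_top)]]
  top_neg <- names(z)[rev(ord)[seq_len(n_top)]]
  top_pos <- setdiff(top_pos, top_neg)   # disjoint by construction except ties
  structure(list(
    explained_variance = fit$explained,
    scores = fit$scores[[1]],
    gene_weights = stats::setNames(w1, colnames(genes)),
    bootstrap_z = z,
    top_positive = top_pos,
    top_negative = top_neg,
    top_fraction = top_fraction
  ), class = "plsr_result")
}

#' @export
print.plsr_result <- function(x, ...) {
  cat(sprintf(
    "plsr_result: %d components; component-1 explained variance = %.3f\n",
    length(x$explained_variance), x$explained_variance[1]))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Over-representation with a spatial-surrogate null
#'
#' Hypergeometric over-representation of a gene list in each gene set
#' (BH-corrected across sets), re-calibrated against a spatial null: the
#' PLSR-plus-selection procedure is repeated on variogram-matched surrogate
#' effect maps, producing a null distribution of enrichment p-values per
#' set; a set is called significant only when the observed p lies below the
#' 5th percentile of its surrogate p-values.
#'
#' @param gene_list Character vector of selected genes.
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param background Character vector of all candidate genes.
#' @param effect_map,genes,distance Inputs needed to regenerate the list on
#'   surrogate maps (as in [plsr_genes()]); `distance` feeds the surrogate
#'   model.
#' @param n_surrogates Number of surrogate maps (1,000 for inference).
#' @param which_tail `"positive"` or `"negative"`: which top-Z list the
#'   surrogate runs should regenerate.
#' @param n_boot Bootstrap resamples inside each surrogate PLSR.
#' @param seed RNG seed.
#' @return Data frame per set: `set`, `n_set`, `n_overlap`, `p_hyper`,
#'   `p_fdr`, `p_surrogate_rank` (fraction of surrogate p-values at or
#'   below the observed), `significant`.
#' @export
enrichment_with_surrogate_null <- function(gene_list, gene_sets, background,
                                           effect_map, genes, distance,
                                           n_surrogates = 1000L,
                                           which_tail = c("positive", "negative"),
                                           n_boot = 100L, seed = 1L) {
  which_tail <- match.arg(which_tail)
  obs <- hypergeom_enrichment(gene_list, gene_sets, background)
  if (!nrow(obs)) return(obs)
  ens <- make_surrogates(effect_map, distance, n = n_surrogates, seed = seed)
  null_p <- matrix(NA_real_, n_surrogates, nrow(obs))
  for (s in seq_len(n_surrogates)) {
    pr <- plsr_genes(ens$maps[s, ], genes, n_components = 1L,
                     n_boot = n_boot, seed = seed + s)
    lst <- if (which_tail == "positive") pr$top_positive else pr$top_negative
    null_p[s, ] <- hypergeom_enrichment(lst, gene_sets[obs$set],
                                        background)$p_hyper
  }
  obs$p_surrogate_rank <- vapply(seq_len(nrow(obs)), function(i) {
    mean(null_p[, i] <= obs$p_hyper[i], na.rm = TRUE)
  }, numeric(1))
  obs$significant <- obs$p_fdr < 0.05 & obs$p_surrogate_rank < 0.05
  obs
}

#' Hypergeometric over-representation of a gene list
#'
#' @param gene_list Selected genes.
#' @param gene_sets Named list of sets.
#' @param background All candidate genes.
#' @return Data frame: `set`, `n_set`, `n_overlap`, `p_hyper`, `p_fdr`.
#'   Sets with no member in the background are skipped.
#' @export
hypergeom_enrichment <- function(gene_list, gene_sets, background) {
  background <- unique(background)
  gene_list <- intersect(gene_list, background)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    if (!length(set)) return(NULL)
    k <- length(intersect(gene_list, set))
    p <- stats::phyper(k - 1, length(set), length(background) - length(set),
                       length(gene_list), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set), n_overlap = k, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), n_set = integer(0),
                      n_overlap = integer(0), p_hyper = numeric(0),
                      p_fdr = numeric(0)))
  }
  out$p_fdr <- stats::p.adjust(out$p_hyper, method = "BH")
  out
}

#' Morphometric PCA and similarity network
#'
#' Z-scores the node-by-feature morphometric matrix, extracts the first
#' principal component (sign fixed so it correlates nonnegatively with the
#' first feature), and builds the morphometric similarity network: the
#' Pearson correlation between the z-scored feature vectors of each node
#' pair (diagonal zeroed).
#'
#' @param features Node-by-feature matrix (typically 5 morphometric
#'   measures; >= 6 nodes).  Constant features are dropped with a warning.
#' @return A `morph_profile`: `pc1`, `explained` (variance share per PC),
#'   `msn` (node-by-node similarity), `loadings`.
#' @export
morph_pca_and_msn <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 6L) stop("need at least 6 nodes", call. = FALSE)
  z <- zscore_cols(features)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  if (stats::cor(pc1, z[, 1]) < 0) {
    pc1 <- -pc1
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  msn <- stats::cor(t(z))
  diag(msn) <- 0
  structure(list(
    pc1 = pc1,
    explained = pc$sdev^2 / sum(pc$sdev^2),
    msn = msn,
    loadings = pc$rotation
  ), class = "morph_profile")
}
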