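# Variogram-matched spatial surrogates.  Brain maps are spatially
# autocorrelated, so naive correlation tests between maps are badly
# miscalibrated; every spatial correlation in the pipeline is instead
# tested against surrogate maps that preserve the empirical semivariogram
# of the source map (random permutation, kernel smoothing at several
# candidate scales, and an affine variogram match).

default_surrogate_params <- function(n_nodes = NULL) {
  list(
    n_bins = 25L,
    cutoff = 0.70,                       # distance percentile for pair inclusion
    scale_fractions = c(0.05, 0.10, 0.20, 0.40),  # k-NN neighborhood sizes
    resample = FALSE
  )
}

#' Binned empirical semivariogram
#'
#' `gamma(h_b)` is the mean of `0.5 * (x_i - x_j)^2` over node pairs whose
#' distance falls in bin `b`; bins are equal-count quantile bins of the
#' pairwise distances up to the `cutoff` distance percentile.
#'
#' @param map Numeric node vector.
#' @param distance Symmetric node distance matrix.
#' @param n_bins Number of distance bins.
#' @param cutoff Distance percentile (0-1] above which pairs are ignored.
#' @return Data frame with `h` (mean bin distance), `gamma`, `n_pairs`.
#' @export
variogram <- function(map, distance, n_bins = 25L, cutoff = 0.70) {
  pm <- variogram_pairs(distance, n_bins, cutoff)
  g <- variogram_curve(matrix(map, ncol = 1), pm)
  data.frame(h = pm$h, gamma = g[, 1], n_pairs = pm$count)
}

# Precompute pair indices and bin assignment for repeated variogram
# evaluation on the same distance matrix.
variogram_pairs <- function(distance, n_bins = 25L, cutoff = 0.70) {
  n <- nrow(distance)
  up <- which(upper.tri(distance))
  d <- distance[up]
  dmax <- stats::quantile(d, cutoff, names = FALSE)
  keep <- d <= dmax
  up <- up[keep]
  d <- d[keep]
  breaks <- unique(stats::quantile(d, seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE))
  if (length(breaks) < 3L) {
    warning("degenerate distance distribution; merged variogram bins",
            call. = FALSE)
  }
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  i <- ((up - 1L) %% n) + 1L
  j <- ((up - 1L) %/% n) + 1L
  count <- tabulate(bin, nbins = length(breaks) - 1L)
  if (any(count == 0L)) {     # can only happen with heavy ties
    keep_bins <- which(count > 0L)
    bin <- match(bin, keep_bins)
    count <- count[keep_bins]
    warning("empty variogram bin merged with neighbor", call. = FALSE)
  }
  h <- as.numeric(rowsum(d, bin)) / count
  list(i = i, j = j, bin = bin, count = count, h = h, n = n)
}

# gamma curves for the columns of M (n_nodes x n_maps): n_bins x n_maps.
variogram_curve <- function(m, pm) {
  d2 <- 0.5 * (m[pm$i, , drop = FALSE] - m[pm$j, , drop = FALSE])^2
  rowsum(d2, pm$bin) / pm$count
}

# k-nearest-neighbor exponential smoothing matrix for one scale fraction.
knn_smoother <- function(distance, fraction) {
  n <- nrow(distance)
  k <- max(3L, ceiling(fraction * n))
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(distance[i, ])[seq_len(k)]
    dk <- distance[i, ord[k]]
    w <- exp(-distance[i, ord] / max(dk, .Machine$double.eps))
    s[i, ord] <- w / sum(w)
  }
  s
}

#' Precompute a surrogate model for a distance matrix
#'
#' Caches the variogram pair structure and the candidate smoothing matrices
#' so ensembles for many maps on the same parcellation are cheap.
#'
#' @param distance Symmetric node distance matrix.
#' @param params Parameter list; see [default_surrogate_params()].
#' @return A `surrogate_model` list.
#' @export
build_surrogate_model <- function(distance, params = list()) {
  params <- utils::modifyList(default_surrogate_params(), params)
  structure(list(
    distance = distance,
    params = params,
    pairs = variogram_pairs(distance, params$n_bins, params$cutoff),
    smoothers = lapply(params$scale_fractions,
                       function(f) knn_smoother(distance, f))
  ), class = "surrogate_model")
}

#' Generate variogram-matched surrogate maps
#'
#' Each surrogate starts as a random permutation of the source map, is
#' smoothed with a distance kernel at each candidate neighborhood scale,
#' and the scale plus affine rescaling (intercept `a`, slope `b`)
#' minimizing the squared distance between the surrogate and empirical
#' variograms is kept; the final surrogate is
#' `sqrt(|b|) * smoothed + sqrt(|a|) * white noise`, which approximately
#' reproduces the source variogram.  With an empty `scale_fractions` the
#' procedure degenerates to a plain permutation null.  With
#' `resample = TRUE` surrogate values are rank-mapped back onto the source
#' values (exact multiset preservation).
#'
#' @param map Numeric node vector.
#' @param distance Symmetric node distance matrix (ignored when `model` is
#'   given).
#' @param n Number of surrogates (use 1,000 for inference).
#' @param params Parameter overrides; see [default_surrogate_params()].
#' @param seed RNG seed.
#' @param model Optional precomputed [build_surrogate_model()] output.
#' @return A `surrogate_ensemble`: `maps` (n x n_nodes), `source_map`,
#'   `params`, `seed`.
#' @export
make_surrogates <- function(map, distance = NULL, n = 1000L, params = list(),
                            seed = 1L, model = NULL) {
  if (n < 1L) stop("need at least one surrogate", call. = FALSE)
  if (is.null(model)) {
    if (is.null(distance)) stop("distance or model required", call. = FALSE)
    model <- build_surrogate_model(distance, params)
  }
  params <- model$params
  nn <- length(map)
  if (nn != model$pairs$n) stop("map length does not match model", call. = FALSE)
  set.seed(seed)
  perm <- vapply(seq_len(n), function(...) sample(map), numeric(nn))
  if (length(model$smoothers) == 0L) {
    out <- t(perm)
  } else {
    v0 <- as.numeric(variogram_curve(matrix(map, ncol = 1), model$pairs))
    best_sse <- rep(Inf, n)
    best_map <- matrix(0, nn, n)
    for (s in model$smoothers) {
      sm <- s %*% perm
      v <- variogram_curve(sm, model$pairs)     # n_bins x n
      mv <- colMeans(v)
      cv <- colMeans(v * v0) - mv * mean(v0)
      vv <- colMeans(v^2) - mv^2
      b <- ifelse(vv > 0, cv / vv, 0)
      a <- mean(v0) - b * mv
      fit <- sweep(v * rep(b, each = nrow(v)), 2, -a)   # b*v + a
      sse <- colSums((fit - v0)^2)
      upd <- sse < best_sse
      if (any(upd)) {
        noise <- matrix(stats::rnorm(nn * sum(upd)), nn)
        best_map[, upd] <- sweep(sm[, upd, drop = FALSE], 2,
                                 sqrt(abs(b[upd])), `*`) +
          sweep(noise, 2, sqrt(abs(a[upd])), `*`)
        best_sse[upd] <- sse[upd]
      }
    }
    out <- t(best_map)
  }
  if (isTRUE(params$resample)) {
    sorted <- sort(map)
    out <- t(apply(out, 1, function(x) sorted[rank(x, ties.method = "first")]))
  }
  structure(list(maps = out, source_map = map, params = params,
                 seed = seed),
            class = "surrogate_ensemble")
}

#' Surrogate-corrected spatial correlation test
#'
#' Correlates two node maps and compares the coefficient with the null
#' distribution of correlations between each surrogate of map A and map B.
#' The p-value uses the add-one continuity correction
#' `(1 + #{null at least as extreme}) / (n_surrogates + 1)`.
#'
#' @param map_a,map_b Numeric node vectors of equal length.
#' @param ensemble A `surrogate_ensemble` built on `map_a`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List: `r`, `p`, `null` (the null correlation vector), `method`,
#'   `alternative`.
#' @export
surrogate_corr_test <- function(map_a, map_b, ensemble,
                                method = c("pearson", "spearman"),
                                alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(map_a) != length(map_b)) stop("map lengths differ", call. = FALSE)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("correlation undefined for a zero-variance map", call. = FALSE)
  }
  r <- stats::cor(map_a, map_b, method = method)
  null <- as.numeric(stats::cor(t(ensemble$maps), map_b, method = method))
  k <- switch(alternative,
              two.sided = sum(abs(null) >= abs(r)),
              greater = sum(null >= r),
              less = sum(null <= r))
  list(r = r, p = (1 + k) / (length(null) + 1), null = null,
       method = method, alternative = alternative)
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("surrogate_ensemble: %d maps of %d nodes (resample = %s)\n",
              nrow(x$maps), ncol(x$maps), x$params$resample))
  invisible(x)
}
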