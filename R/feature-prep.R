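# Preparation of the three structural feature matrices: microstructural
# profile covariance (MPC) from depth profiles, log-transformed tract
# strength (TS), and inverted geodesic distance (GD), each rank-normalized
# and rescaled to a common [0, 1] range before fusion.

#' Symmetric structural feature matrix
#'
#' Light container for one node-by-node structural feature.  The mask marks
#' entries treated as present (by default the nonzero off-diagonal entries);
#' downstream rank normalization operates only on masked entries.
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param kind One of `"GD"`, `"MPC"`, `"TS"`.
#' @param mask Optional logical matrix; defaults to `values != 0` off the
#'   diagonal.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, kind = c("GD", "MPC", "TS"), mask = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-10) {
    stop("feature matrix must be symmetric (tol 1e-10)", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(mask)) mask <- values != 0
  diag(mask) <- FALSE
  mask <- mask & t(mask)
  if (kind == "TS" && any(values[mask] < 0)) {
    stop("tract strength must be nonnegative", call. = FALSE)
  }
  structure(list(values = values, kind = kind, mask = mask),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s] %d x %d, %d masked entries\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Microstructural profile covariance from depth profiles
#'
#' For each pair of nodes, the partial Pearson correlation between their
#' depth-wise intensity profiles, controlling for the cortex-mean profile
#' (both profiles are residualized on the mean profile across nodes, with
#' intercept, and the residuals correlated).  Negative partials are
#' thresholded at zero and the remainder mapped through the Fisher
#' transform `r -> ln((1 + r) / (1 - r))` (finite at r = 0, monotone), with
#' r clipped to `1 - 1e-12` beforehand.  The diagonal is zero.
#'
#' @param profiles Node-by-depth intensity matrix (>= 3 depths, >= 3 nodes).
#' @param transform `"fisher"` (default) for `ln((1+r)/(1-r))`, or `"log"`
#'   for `ln(1 + r)` applied to the thresholded partials.
#' @return A `feature_matrix` of kind `"MPC"`.  Zero-variance nodes yield a
#'   zeroed row/column with a warning.
#' @export
compute_mpc <- function(profiles, transform = c("fisher", "log")) {
  transform <- match.arg(transform)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 3L || ncol(profiles) < 3L) {
    stop("need at least 3 nodes and 3 depths", call. = FALSE)
  }
  mean_profile <- colMeans(profiles)
  q <- qr(cbind(1, mean_profile))
  resid <- t(qr.resid(q, t(profiles)))          # node x depth residuals
  rs <- sqrt(rowSums(resid^2))
  bad <- rs < 1e-12
  if (any(bad)) {
    warning(sprintf("%d node(s) with zero-variance residual profile zeroed",
                    sum(bad)), call. = FALSE)
    rs[bad] <- 1
  }
  u <- resid / rs
  r <- tcrossprod(u)
  r[bad, ] <- 0
  r[, bad] <- 0
  r[r < 0] <- 0
  r <- pmin(r, 1 - 1e-12)
  m <- if (transform == "fisher") log((1 + r) / (1 - r)) else log1p(r)
  diag(m) <- 0
  feature_matrix(m, "MPC")
}

#' Log-transform streamline counts
#'
#' Masked (nonzero) entries are mapped through `ln(1 + x)`; zero entries
#' stay zero and unmasked.  Negative counts are an error.
#'
#' @param counts A `feature_matrix` of kind `"TS"`, or a plain matrix.
#' @return A `feature_matrix` of kind `"TS"`.
#' @export
log_transform_ts <- function(counts) {
  if (!inherits(counts, "feature_matrix")) counts <- feature_matrix(counts, "TS")
  if (any(counts$values < 0)) stop("negative streamline count", call. = FALSE)
  v <- counts$values
  v[counts$mask] <- log1p(v[counts$mask])
  feature_matrix(v, "TS", mask = counts$mask)
}

#' Rank-normalize and rescale a feature matrix
#'
#' The masked entries of the upper triangle are replaced by average-tie
#' ranks, min-max rescaled to `[0, 1]`, and mirrored to keep symmetry.
#' With `invert = TRUE` (used for geodesic distance) the rescaled value `v`
#' becomes `1 - v`, so spatial proximity maps to high affinity.  Unmasked
#' entries stay zero.
#'
#' @param m A `feature_matrix`.
#' @param invert Flip the rescaled values (`v -> 1 - v`).
#' @return A `feature_matrix` of the same kind with values in `[0, 1]`.
#' @export
rank_normalize_rescale <- function(m, invert = FALSE) {
  stopifnot(inherits(m, "feature_matrix"))
  up <- upper.tri(m$values) & m$mask
  x <- m$values[up]
  if (length(x) < 2L) stop("need at least 2 masked entries", call. = FALSE)
  r <- rank(x, ties.method = "average")
  if (max(r) == min(r)) {
    warning("all masked values identical; mapping to 0.5", call. = FALSE)
    v <- rep(0.5, length(r))
  } else {
    v <- (r - min(r)) / (max(r) - min(r))
  }
  if (invert) v <- 1 - v
  out <- matrix(0, nrow(m$values), ncol(m$values))
  out[up] <- v
  out <- out + t(out)
  feature_matrix(out, m$kind, mask = m$mask)
}

#' Prepare the three fused-model inputs from one scan
#'
#' Convenience wrapper running the full preparation: MPC from depth
#' profiles, `ln(1 + x)` tract strength, and inverted geodesic distance,
#' each rank-normalized and rescaled to `[0, 1]`.
#'
#' @param scan A `scan_record` (or any list with `gd`, `profiles`, `ts`).
#' @param mpc_transform Passed to [compute_mpc()].
#' @return Named list of three `feature_matrix` objects: `gd`, `mpc`, `ts`.
#' @export
prepare_features <- function(scan, mpc_transform = "fisher") {
  list(
    gd = rank_normalize_rescale(feature_matrix(scan$gd, "GD"), invert = TRUE),
    mpc = rank_normalize_rescale(compute_mpc(scan$profiles, mpc_transform)),
    ts = rank_normalize_rescale(log_transform_ts(feature_matrix(scan$ts, "TS")))
  )
}
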