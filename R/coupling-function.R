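# Functional-connectivity processing: the primary-to-transmodal FC
# gradient, nodal structure-function coupling, participation coefficients,
# and gradient-space differentiation distances.

#' Functional-connectivity gradient
#'
#' Row-thresholds the FC matrix to its top 10% largest off-diagonal entries
#' (others zeroed; the thresholded matrix is used asymmetrically as row
#' profiles), computes normalized-angle similarity between rows, and embeds
#' with the diffusion map.  Component 1 is the primary-to-transmodal proxy.
#'
#' @param fc Symmetric correlation matrix (diagonal 1).
#' @param k Number of embedding components.
#' @param threshold Fraction of entries kept per row (default 0.10).
#' @param alpha Diffusion anisotropy parameter.
#' @return A `gradient_set`.
#' @export
fc_gradient <- function(fc, k = 10L, threshold = 0.10, alpha = 0.5) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  keep_n <- max(1L, floor(threshold * (n - 1L)))
  thr <- fc
  diag(thr) <- -Inf
  warned <- FALSE
  for (i in seq_len(n)) {
    row <- thr[i, ]
    cut <- sort(row, decreasing = TRUE)[keep_n]
    drop <- row < cut
    if (sum(row[!drop] > 0) < keep_n && !warned) {
      warning("some rows have fewer than the requested positive edges",
              call. = FALSE)
      warned <- TRUE
    }
    thr[i, drop] <- 0
  }
  thr[thr == -Inf] <- 0
  thr[thr < 0] <- 0
  aff <- normalized_angle_affinity(thr, source = "fc")
  diffusion_map(aff, k = k, alpha = alpha)
}

#' Nodal structure-function coupling
#'
#' For each node, the Spearman rank correlation between its row of the
#' fused multiscale structural affinity and its row of FC, excluding the
#' self-entry in both profiles.
#'
#' @param ms_affinity An `affinity_matrix` (fused structural) or matrix.
#' @param fc Symmetric FC matrix over the same node set.
#' @return Numeric vector of per-node Spearman rho (`NA` where a profile is
#'   constant).
#' @export
nodal_coupling <- function(ms_affinity, fc) {
  a <- if (inherits(ms_affinity, "affinity_matrix")) ms_affinity$values else
    as.matrix(ms_affinity)
  fc <- as.matrix(fc)
  n <- nrow(a)
  if (nrow(fc) != n) stop("node sets differ", call. = FALSE)
  vapply(seq_len(n), function(i) {
    x <- a[i, -i]
    y <- fc[i, -i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
}

#' Participation coefficient of a weighted modular graph
#'
#' `PaC_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` is the summed weight
#' from node i into community s and `k_i` its total strength; nodes with
#' zero strength get 0.  Quantifies inter-module connectivity: 0 when all
#' strength stays within one community, approaching `1 - 1/S` for a uniform
#' spread over S communities.
#'
#' @param w Nonnegative symmetric weight matrix with zero diagonal (rectify
#'   FC to its positive part before calling).
#' @param communities Community label per node.
#' @return Numeric vector of participation coefficients.
#' @export
participation_coefficient <- function(w, communities) {
  w <- as.matrix(w)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  diag(w) <- 0
  communities <- as.factor(communities)
  if (length(communities) != nrow(w)) stop("label per node required", call. = FALSE)
  ind <- stats::model.matrix(~ communities - 1)
  kis <- w %*% ind                      # node x community strengths
  ki <- rowSums(kis)
  pac <- 1 - rowSums((kis / ifelse(ki > 0, ki, 1))^2)
  pac[ki == 0] <- 0
  as.numeric(pac)
}

#' Within- and between-community differentiation distances
#'
#' Pairwise Euclidean distances in the 2-D gradient (wiring) space,
#' averaged within each community and between each community pair — an
#' index of multiscale structural differentiation of the community layout.
#'
#' @param space A `gradient_space_2d`.
#' @param communities Community label per node (>= 2 communities).
#' @return Data frame with `community_a`, `community_b` (equal on the
#'   within rows), `mean_distance`, `n_pairs`.
#' @export
differentiation_distance <- function(space, communities) {
  stopifnot(inherits(space, "gradient_space_2d"))
  communities <- as.factor(communities)
  if (nlevels(communities) < 2L) stop("need at least 2 communities", call. = FALSE)
  d <- as.matrix(stats::dist(space$points))
  lv <- levels(communities)
  res <- list()
  for (ai in seq_along(lv)) {
    for (bi in ai:length(lv)) {
      ia <- which(communities == lv[ai])
      ib <- which(communities == lv[bi])
      sub <- d[ia, ib, drop = FALSE]
      if (ai == bi) {
        vals <- sub[upper.tri(sub)]
        if (!length(vals)) vals <- 0
      } else {
        vals <- as.numeric(sub)
      }
      res[[length(res) + 1L]] <- data.frame(
        community_a = lv[ai], community_b = lv[bi],
        mean_distance = mean(vals), n_pairs = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
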