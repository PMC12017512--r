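# Global and regional gradient descriptors: range, explanation ratio,
# standard deviation, the 2-D gradient space of components 1 and 3, its
# dispersion and per-node eccentricity, and community-level summaries.

#' Two-dimensional gradient space
#'
#' The plane spanned by two embedding components (by convention the first
#' and third, which carry the primary-transmodal and anterior-posterior
#' axes).
#'
#' @param g A `gradient_set` (or a plain node-by-k matrix).
#' @param components Length-2 index vector, default `c(1, 3)`.
#' @return A `gradient_space_2d` list: `points` (node x 2), `centroid`.
#' @export
gradient_space <- function(g, components = c(1L, 3L)) {
  m <- if (inherits(g, "gradient_set")) g$components else as.matrix(g)
  stopifnot(length(components) == 2L, max(components) <= ncol(m))
  pts <- m[, components, drop = FALSE]
  structure(list(points = pts, centroid = colMeans(pts)),
            class = "gradient_space_2d")
}

#' Global measures of one gradient component
#'
#' @param g A `gradient_set`.
#' @param component Component index.
#' @return Named list: `range` (max minus min score), `explanation_ratio`,
#'   `sd` (population standard deviation of the scores).
#' @export
global_measures <- function(g, component = 1L) {
  stopifnot(inherits(g, "gradient_set"),
            component >= 1L, component <= ncol(g$components))
  x <- g$components[, component]
  list(
    range = max(x) - min(x),
    explanation_ratio = g$explanation_ratio[component],
    sd = sqrt(mean((x - mean(x))^2))
  )
}

#' Gradient-space dispersion
#'
#' Sum of the Euclidean distances of each node to the centroid of the 2-D
#' gradient space; a global index of how spread out (differentiated) the
#' embedding is.
#'
#' @param space A `gradient_space_2d`.
#' @return Scalar dispersion.
#' @export
dispersion <- function(space) {
  stopifnot(inherits(space, "gradient_space_2d"))
  d <- sweep(space$points, 2, space$centroid)
  sum(sqrt(rowSums(d^2)))
}

#' Per-node eccentricity relative to a template centroid
#'
#' Euclidean distance of each node to the centroid of the template gradient
#' space (from the all-scan average connectome), so individual scans are
#' measured in a common frame.
#'
#' @param space A `gradient_space_2d` for the individual.
#' @param template_centroid Length-2 centroid of the template space.
#' @return Numeric vector, one value per node.
#' @export
eccentricity <- function(space, template_centroid) {
  stopifnot(inherits(space, "gradient_space_2d"),
            length(template_centroid) == 2L)
  d <- sweep(space$points, 2, template_centroid)
  sqrt(rowSums(d^2))
}

#' Community-level summary of a gradient component
#'
#' Mean and population standard deviation of the chosen component per
#' community, with optional differences against a reference summary (for
#' radar-style comparison of age groups against the youngest).
#'
#' @param g A `gradient_set`.
#' @param parcels A `parcel_set` supplying the community labels.
#' @param component Component index.
#' @param reference Optional data frame from a previous call; adds a
#'   `diff_mean` column (this mean minus reference mean).
#' @return Data frame with `community`, `n`, `mean`, `sd` (and `diff_mean`).
#' @export
community_summary <- function(g, parcels, component = 1L, reference = NULL) {
  x <- g$components[, component]
  labels <- parcels$community
  if (anyNA(labels)) stop("missing community label", call. = FALSE)
  sp <- split(x, labels)
  out <- data.frame(
    community = names(sp),
    n = vapply(sp, length, 1L),
    mean = vapply(sp, mean, 1),
    sd = vapply(sp, function(v) sqrt(mean((v - mean(v))^2)), 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(reference)) {
    m <- match(out$community, reference$community)
    out$diff_mean <- out$mean - reference$mean[m]
  }
  out
}
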