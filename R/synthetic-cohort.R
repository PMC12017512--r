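# Synthetic longitudinal cohort with planted gradient effects.
#
# The generator produces everything the downstream pipeline consumes:
# a spherical parcellation, per-scan structural feature payloads (geodesic
# distance, depth-wise intensity profiles, streamline counts), functional
# connectivity, behavior scores coupled to the planted axis, and spatially
# autocorrelated gene expression maps.  A PlantedTruth object records the
# ground truth so recovery can be tested.

#' Construct a spherical parcellation
#'
#' Places `n_nodes` parcels on the unit sphere along a Fibonacci spiral,
#' splits them into hemispheres by the sign of the x coordinate, and assigns
#' community labels by contiguous latitude bands (a stand-in for intrinsic
#' functional communities).  The construction is deterministic; `seed` is
#' accepted for interface uniformity with the other simulators.
#'
#' @param n_nodes Number of parcels (must be at least `4 * n_communities`).
#' @param n_communities Number of community labels (>= 2).
#' @param seed Unused RNG seed, kept so all simulators share a signature.
#' @return A `parcel_set` data frame with columns `node_id` (0-based,
#'   contiguous), `x`, `y`, `z` (unit-norm coordinates), `hemisphere`
#'   (`"L"`/`"R"`), and `community`.
#' @examples
#' p <- make_parcels(100, 4)
#' table(p$community)
#' @export
make_parcels <- function(n_nodes, n_communities = 4L, seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  n_communities <- as.integer(n_communities)
  if (n_communities < 2L) stop("need at least 2 communities", call. = FALSE)
  if (n_nodes < 4L * n_communities) {
    stop("n_nodes must be at least 4 * n_communities", call. = FALSE)
  }
  i <- seq_len(n_nodes) - 1L
  z <- 1 - 2 * (i + 0.5) / n_nodes
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  x <- r * cos(phi)
  y <- r * sin(phi)
  # contiguous latitude bands, as equal in size as divisibility allows
  band <- ceiling(rank(-z, ties.method = "first") * n_communities / n_nodes)
  parcels <- data.frame(
    node_id = i,
    x = x, y = y, z = z,
    hemisphere = ifelse(x < 0, "L", "R"),
    community = paste0("C", band),
    stringsAsFactors = FALSE
  )
  class(parcels) <- c("parcel_set", "data.frame")
  parcels
}

#' Great-circle distance matrix of a parcel set
#'
#' Pairwise great-circle (arc length on the unit sphere) distances between
#' parcel centroids; the package's stand-in for cortical geodesic distance.
#'
#' @param parcels A `parcel_set`.
#' @return Symmetric `n x n` matrix with zero diagonal, entries in `[0, pi]`.
#' @export
parcel_distance <- function(parcels) {
  xyz <- as.matrix(parcels[, c("x", "y", "z")])
  cosd <- tcrossprod(xyz)
  cosd[cosd > 1] <- 1
  cosd[cosd < -1] <- -1
  d <- acos(cosd)
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Define the planted ground truth of a synthetic cohort
#'
#' The planted effect is a smooth primary-vs-transmodal contrast across the
#' parcellation whose amplitude scales with age; behavior scores and gene
#' maps are coupled to it.  The contrast defaults to the standardized
#' latitude (z coordinate), which is spatially smooth on the sphere so the
#' variogram-matching surrogates have realistic autocorrelation to preserve.
#'
#' @param parcels A `parcel_set`.
#' @param age_slope Per-year scaling of the contrast amplitude (1/year).
#' @param contrast_vector Optional per-node loading; standardized internally
#'   to zero mean and unit population variance.
#' @param behavior_weights Numeric vector mapping the subject-level realized
#'   contrast amplitude to behavior scores (one score per element).
#' @param gene_effect_map Optional per-node target map for PLSR recovery
#'   tests; defaults to the contrast vector.
#' @param autocorr_length Range parameter (radians of arc) of the
#'   exponential spatial kernel used for autocorrelated noise fields.
#' @param noise Named list of noise magnitudes; see Details.
#' @param seed RNG seed stored with the truth object.
#' @details The `noise` list exposes every stochastic magnitude of the
#'   generator: `profile` (depth-profile intensity sd), `gd_jitter`
#'   (positive jitter added to distances), `ts_size` (negative-binomial
#'   dispersion of streamline counts), `ts_scale` (expected count at zero
#'   distance), `ts_lambda` (distance-decay length of counts),
#'   `community_bonus` (within-community count multiplier), `fc_block`
#'   (community block signal added before FC construction), `fc_noise`
#'   (sd of the noise entering FC), `subject_sd` (sd of the per-subject
#'   random intercept on the contrast amplitude), `latent_sd` (scan-level
#'   jitter of the behavior latent), and `behavior_sd` (per-score noise).
#' @return A `planted_truth` list.
#' @export
planted_truth <- function(parcels,
                          age_slope = 0.05,
                          contrast_vector = NULL,
                          behavior_weights = c(1, 0.8, -0.6, 0.4),
                          gene_effect_map = NULL,
                          autocorr_length = 0.2,
                          noise = list(),
                          seed = 1L) {
  if (autocorr_length <= 0) stop("autocorr_length must be positive", call. = FALSE)
  n <- nrow(parcels)
  if (is.null(contrast_vector)) contrast_vector <- parcels$z
  contrast_vector <- standardize_pop(contrast_vector)
  if (is.null(gene_effect_map)) gene_effect_map <- contrast_vector
  defaults <- list(
    profile = 0.30, gd_jitter = 0.02,
    ts_size = 4, ts_scale = 30, ts_lambda = 0.75, community_bonus = 0.5,
    fc_block = 0.15, fc_noise = 0.20, fc_ridge = 0.10,
    subject_sd = 0.15, latent_sd = 0.15, behavior_sd = 0.30
  )
  noise <- utils::modifyList(defaults, noise)
  # communities at the positive end of the contrast act as the primary proxy
  comm_means <- tapply(contrast_vector, parcels$community, mean)
  structure(list(
    contrast_vector = contrast_vector,
    age_slope = age_slope,
    behavior_weights = behavior_weights,
    gene_effect_map = gene_effect_map,
    autocorr_length = autocorr_length,
    noise = noise,
    primary_community = names(which.max(comm_means)),
    seed = as.integer(seed)
  ), class = "planted_truth")
}

standardize_pop <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) stop("contrast vector has zero variance", call. = FALSE)
  x / s
}

# Fixed depth-sampling geometry shared by all scans: a declining baseline
# intensity profile plus a mid-depth bump that carries the planted contrast.
profile_shapes <- function(n_depths = 12L) {
  d <- seq_len(n_depths)
  list(
    base = seq(1.5, 0.5, length.out = n_depths),
    loading = sin(pi * d / (n_depths + 1))
  )
}

#' Simulate one scan's raw feature payloads
#'
#' Generates geodesic distance, depth profiles, streamline counts,
#' functional connectivity, and behavior for a single scan.  The planted
#' contrast enters the depth profiles with amplitude
#' `(1 + age * age_slope + subject intercept)`, so microstructural
#' similarity is higher between nodes on the same end of the contrast and
#' the downstream principal gradient inherits the planted axis.
#'
#' @param parcels A `parcel_set`.
#' @param truth A `planted_truth`.
#' @param age Age in years.
#' @param subject_state List with elements `subject_id`, `intercept`
#'   (per-subject amplitude offset), `sex` (0/1), and optionally `latent_shift`.
#' @param scan_id Identifier for this scan.
#' @param n_depths Number of intracortical sampling depths (>= 3).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as when called from [simulate_cohort()]).
#' @param motion Optional head-motion covariate; drawn if `NULL`.
#' @return A `scan_record` list with fields `subject_id`, `scan_id`, `age`,
#'   `sex`, `motion`, `gd`, `profiles`, `ts`, `fc`, `behavior`, `latent`.
#' @export
simulate_scan <- function(parcels, truth, age,
                          subject_state = list(subject_id = "s1", intercept = 0, sex = 0L),
                          scan_id = "s1_t1", n_depths = 12L, seed = NULL,
                          motion = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(parcels)
  nz <- truth$noise
  d0 <- parcel_distance(parcels)

  # geodesic distance: metric base plus small positive jitter
  jit <- matrix(0, n, n)
  up <- upper.tri(jit)
  jit[up] <- abs(stats::rnorm(sum(up), 0, nz$gd_jitter))
  gd <- d0 + jit + t(jit)
  diag(gd) <- 0

  # depth profiles carrying the age-scaled contrast
  shapes <- profile_shapes(n_depths)
  amp <- 1 + age * truth$age_slope + subject_state$intercept
  a <- amp * truth$contrast_vector
  profiles <- outer(rep(1, n), shapes$base) + outer(a, shapes$loading) +
    matrix(stats::rnorm(n * n_depths, 0, nz$profile), n, n_depths)
  rownames(profiles) <- parcels$node_id

  # streamline counts: negative binomial with exponential distance decay
  same_comm <- outer(parcels$community, parcels$community, "==")
  mu <- nz$ts_scale * exp(-d0 / nz$ts_lambda) * (1 + nz$community_bonus * same_comm)
  ts <- matrix(0, n, n)
  ts[up] <- stats::rnbinom(sum(up), mu = mu[up], size = nz$ts_size)
  ts <- ts + t(ts)
  diag(ts) <- 0

  # functional connectivity: monotone-ish transform of the fused structural
  # affinity plus community block signal, returned as a correlation matrix
  aff <- build_multiscale_affinity(
    rank_normalize_rescale(feature_matrix(gd, "GD"), invert = TRUE),
    rank_normalize_rescale(compute_mpc(profiles)),
    rank_normalize_rescale(log_transform_ts(feature_matrix(ts, "TS")))
  )$values
  sig <- aff + nz$fc_block * same_comm
  en <- matrix(stats::rnorm(n * n, 0, nz$fc_noise), n, n)
  g <- sig + (en + t(en)) / sqrt(2)
  fc <- stats::cov2cor(tcrossprod(g) / n + nz$fc_ridge * diag(n))

  # behavior coupled to the realized contrast amplitude
  latent <- age * truth$age_slope + subject_state$intercept +
    stats::rnorm(1, 0, nz$latent_sd)
  behavior <- truth$behavior_weights * latent +
    stats::rnorm(length(truth$behavior_weights), 0, nz$behavior_sd)

  structure(list(
    subject_id = subject_state$subject_id,
    scan_id = scan_id,
    age = age,
    sex = subject_state$sex,
    motion = if (is.null(motion)) abs(stats::rnorm(1, 0.15, 0.05)) else motion,
    gd = gd, profiles = profiles, ts = ts, fc = fc,
    behavior = behavior, latent = latent
  ), class = "scan_record")
}

#' Simulate an accelerated-longitudinal scan design
#'
#' Draws the phenotype skeleton of a cohort without generating feature
#' payloads: subjects receive 1-3 scans (default mixing proportions
#' 159/83/39 out of 276) with within-subject age increments of at least
#' half a year, subject-level sex and random intercepts, and per-scan
#' motion covariates.
#'
#' @inheritParams simulate_cohort
#' @param subject_sd Standard deviation of the per-subject random
#'   intercept (stored in `attr(, "intercepts")`).
#' @return Data frame with `subject_id`, `scan_id`, `age`, `sex`,
#'   `motion`, plus attributes `intercepts` (named per subject).
#' @export
simulate_design <- function(n_subjects = 100L,
                            scan_probs = c(`1` = 159, `2` = 83, `3` = 39) / 276,
                            age_range = c(6, 14), subject_sd = 0.15,
                            seed = 1L) {
  if (n_subjects < 10L) stop("need at least 10 subjects", call. = FALSE)
  scan_probs <- scan_probs / sum(scan_probs)
  max_scans <- length(scan_probs)
  if (diff(age_range) < 0.5 * (max_scans - 1)) {
    stop("age range too narrow for the required within-subject increments",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_subjects)
  intercepts <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("sub%03d", s)
    k <- sample.int(max_scans, 1, prob = scan_probs)
    inc <- if (k > 1) stats::runif(k - 1, 0.5, 1.5) else numeric(0)
    if (sum(inc) > diff(age_range)) inc <- inc * diff(age_range) / sum(inc)
    base <- stats::runif(1, age_range[1], age_range[2] - sum(inc))
    intercepts[s] <- stats::rnorm(1, 0, subject_sd)
    rows[[s]] <- data.frame(
      subject_id = sid,
      scan_id = sprintf("%s_t%d", sid, seq_len(k)),
      age = base + cumsum(c(0, inc)),
      sex = stats::rbinom(1, 1, 0.5),
      motion = abs(stats::rnorm(k, 0.15, 0.05)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "intercepts") <- stats::setNames(intercepts,
                                             sprintf("sub%03d",
                                                     seq_len(n_subjects)))
  out
}

#' Simulate an accelerated-longitudinal cohort
#'
#' Each subject receives 1-3 scans (mixing proportions default to the
#' 159/83/39-out-of-276 design of an accelerated longitudinal child cohort)
#' with within-subject age increments of at least half a year.  A
#' per-subject random intercept perturbs the planted contrast amplitude in
#' every feature, so the mixed age model's random effect term is real.
#'
#' @param parcels A `parcel_set`.
#' @param truth A `planted_truth`.
#' @param n_subjects Number of subjects (>= 10).
#' @param scan_probs Named numeric vector of probabilities for 1, 2, 3 scans.
#' @param age_range Length-2 numeric, years.
#' @param n_depths Depth samples per profile.
#' @param seed RNG seed; the whole cohort is reproducible given the seed.
#' @return A `synthetic_cohort` list: `scans` (list of `scan_record`),
#'   `phenotypes` (one row per scan: subject_id, scan_id, age, sex, motion,
#'   behavior columns), `parcels`, `truth`.
#' @export
simulate_cohort <- function(parcels, truth, n_subjects = 100L,
                            scan_probs = c(`1` = 159, `2` = 83, `3` = 39) / 276,
                            age_range = c(6, 14), n_depths = 12L, seed = 1L) {
  design <- simulate_design(n_subjects, scan_probs, age_range,
                            subject_sd = truth$noise$subject_sd, seed = seed)
  intercepts <- attr(design, "intercepts")
  scans <- vector("list", nrow(design))
  names(scans) <- design$scan_id
  beh <- matrix(NA_real_, nrow(design), length(truth$behavior_weights))
  for (r in seq_len(nrow(design))) {
    state <- list(
      subject_id = design$subject_id[r],
      intercept = intercepts[[design$subject_id[r]]],
      sex = design$sex[r]
    )
    sc <- simulate_scan(parcels, truth, design$age[r], state,
                        scan_id = design$scan_id[r], n_depths = n_depths,
                        motion = design$motion[r])
    scans[[r]] <- sc
    beh[r, ] <- sc$behavior
  }
  colnames(beh) <- paste0("beh", seq_len(ncol(beh)))
  phen <- cbind(design, as.data.frame(beh))
  attr(phen, "intercepts") <- intercepts
  structure(list(
    scans = scans,
    phenotypes = phen,
    parcels = parcels,
    truth = truth
  ), class = "synthetic_cohort")
}

#' Spatially autocorrelated Gaussian maps on the parcellation
#'
#' Smooths white noise with an exponential kernel `exp(-d / length_scale)`
#' and standardizes each map to zero mean and unit population variance.
#' Used for gene-expression noise fields and for calibration experiments.
#'
#' @param distance Symmetric distance matrix.
#' @param length_scale Kernel range, in the units of `distance`.
#' @param n Number of maps.
#' @param seed Optional seed.
#' @return `nrow(distance) x n` matrix, one map per column.
#' @export
simulate_autocorrelated_maps <- function(distance, length_scale, n = 1L,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- exp(-distance / length_scale)
  m <- k %*% matrix(stats::rnorm(nrow(distance) * n), ncol = n)
  apply(m, 2, standardize_pop, simplify = TRUE)
}

#' Simulate a region-by-gene expression matrix
#'
#' Signal genes are the planted `gene_effect_map` at a fixed loading plus
#' spatially autocorrelated noise; null genes are pure autocorrelated noise
#' with range `truth$autocorr_length`.
#'
#' @param parcels A `parcel_set`.
#' @param truth A `planted_truth`.
#' @param n_genes Total number of genes.
#' @param n_signal_genes Number of signal genes (first columns; also in
#'   `attr(, "signal_genes")`).
#' @param loading Correlation-scale loading of signal genes on the map.
#' @param seed RNG seed.
#' @return `n_nodes x n_genes` matrix with gene names `g0001...` in columns.
#' @export
simulate_gene_matrix <- function(parcels, truth, n_genes = 500L,
                                 n_signal_genes = 50L, loading = 0.8,
                                 seed = 1L) {
  if (n_signal_genes >= n_genes) {
    stop("n_signal_genes must be smaller than n_genes", call. = FALSE)
  }
  set.seed(seed)
  d <- parcel_distance(parcels)
  noise <- simulate_autocorrelated_maps(d, truth$autocorr_length, n_genes)
  eff <- standardize_pop(truth$gene_effect_map)
  genes <- noise
  if (n_signal_genes > 0) {
    idx <- seq_len(n_signal_genes)
    genes[, idx] <- loading * eff +
      sqrt(max(0, 1 - loading^2)) * noise[, idx, drop = FALSE]
  }
  colnames(genes) <- sprintf("g%04d", seq_len(n_genes))
  rownames(genes) <- parcels$node_id
  attr(genes, "signal_genes") <- colnames(genes)[seq_len(n_signal_genes)]
  genes
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted truth:", length(x$contrast_vector), "nodes, age_slope =",
      x$age_slope, "per year\n")
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$scans), "scans,",
      length(unique(x$phenotypes$subject_id)), "subjects, ages",
      sprintf("%.1f-%.1f", min(x$phenotypes$age), max(x$phenotypes$age)), "\n")
  invisible(x)
}
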