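# Penalized-spline mixed age models.  Responses are modeled with a cubic
# regression spline in age (smoothing by REML), sex and motion as linear
# covariates, and a per-subject random intercept; the age-effect size is
# the signed change in adjusted R^2 between the full model and a reduced
# model without the age term, with the sign taken from the equivalent
# linear model's age coefficient.

age_model_frame <- function(y, phenotypes) {
  req <- c("age", "sex", "motion", "subject_id")
  missing <- setdiff(req, names(phenotypes))
  if (length(missing)) {
    stop("phenotypes missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(y) != nrow(phenotypes)) {
    stop("response length does not match phenotype rows", call. = FALSE)
  }
  data.frame(y = y, age = phenotypes$age, sex = phenotypes$sex,
             motion = phenotypes$motion,
             subject = factor(phenotypes$subject_id))
}

#' Fit the penalized-spline age model
#'
#' Fits `y ~ s(age, bs = "cr", k = k) + sex + motion [+ s(subject, bs = "re")]`
#' by REML with `mgcv`.  The smooth-term p-value is the standard
#' approximate Wald-type test on the penalized spline coefficients.
#'
#' @param y Per-scan response vector.
#' @param phenotypes Data frame with `age`, `sex`, `motion`, `subject_id`
#'   (one row per scan, same order as `y`).
#' @param k Maximum basis complexity of the age spline (default 3).
#' @param random_intercept Include the per-subject random intercept (drop it
#'   for cross-sectional replication designs).
#' @return List: `fit` (the `gam` object), `adj_r2`, `p_smooth`, `fitted`.
#' @export
fit_age_model <- function(y, phenotypes, k = 3L, random_intercept = TRUE) {
  df <- age_model_frame(y, phenotypes)
  if (nrow(df) < 20L) stop("need at least 20 scans", call. = FALSE)
  n_ages <- length(unique(df$age))
  if (n_ages < 2L) stop("need at least 2 distinct ages", call. = FALSE)
  if (k > n_ages) stop("k exceeds the number of distinct ages", call. = FALSE)
  if (random_intercept) {
    # bam + discrete fREML: same model family, much faster with a
    # many-level random-intercept smooth
    fit <- mgcv::bam(
      y ~ s(age, bs = "cr", k = k) + sex + motion + s(subject, bs = "re"),
      data = df, method = "fREML", discrete = TRUE)
  } else {
    fit <- mgcv::gam(y ~ s(age, bs = "cr", k = k) + sex + motion,
                     data = df, method = "REML")
  }
  sm <- summary(fit)
  list(fit = fit,
       adj_r2 = sm$r.sq,
       p_smooth = unname(sm$s.table["s(age)", "p-value"]),
       fitted = stats::fitted(fit))
}

#' Signed age-effect size (delta adjusted R-squared)
#'
#' Fits the full spline model and a reduced model excluding the age smooth
#' (same covariates and random intercept), computes the absolute change in
#' adjusted R^2, and signs it by the age coefficient of the equivalent
#' linear model `y ~ age + sex + motion`.  Zero-variance responses
#' short-circuit to an effect of 0 with p = 1.
#'
#' @inheritParams fit_age_model
#' @return List: `delta_adj_r2` (signed), `p` (smooth-term p-value),
#'   `adj_r2_full`, `adj_r2_reduced`, `sign`, `full` (fit list or `NULL`).
#' @export
delta_adj_r2 <- function(y, phenotypes, k = 3L, random_intercept = TRUE) {
  if (stats::var(y) < 1e-24) {
    return(list(delta_adj_r2 = 0, p = 1, adj_r2_full = NA_real_,
                adj_r2_reduced = NA_real_, sign = 0, full = NULL))
  }
  full <- fit_age_model(y, phenotypes, k = k,
                        random_intercept = random_intercept)
  df <- age_model_frame(y, phenotypes)
  reduced <- if (random_intercept) {
    mgcv::bam(y ~ sex + motion + s(subject, bs = "re"), data = df,
              method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(y ~ sex + motion, data = df, method = "REML")
  }
  adj_red <- summary(reduced)$r.sq
  lin <- stats::lm(y ~ age + sex + motion, data = df)
  sgn <- sign(stats::coef(lin)[["age"]])
  list(delta_adj_r2 = sgn * abs(full$adj_r2 - adj_red),
       p = full$p_smooth,
       adj_r2_full = full$adj_r2,
       adj_r2_reduced = adj_red,
       sign = sgn,
       full = full)
}

#' Node-wise age effects with Bonferroni correction
#'
#' Applies [delta_adj_r2()] to every node's scan-by-node score column and
#' evaluates the fitted developmental trajectory of each node on an age
#' grid with covariates at reference levels (sex and motion at their means,
#' random intercept excluded).
#'
#' @param scores Scan-by-node matrix of (aligned) gradient scores.
#' @param phenotypes As in [fit_age_model()].
#' @param k Spline basis complexity.
#' @param alpha Family-wise significance level before Bonferroni division.
#' @param grid_length Number of ages in the trajectory grid.
#' @param random_intercept Include the per-subject random intercept.
#' @return An `age_effect_map` list: `effects` (data frame: `node`,
#'   `delta_adj_r2`, `p`, `significant`), `trajectories`
#'   (grid-by-node matrix), `age_grid`, `alpha`, `n_tests`.  Nodes whose
#'   fit fails are recorded with `NA` effects rather than aborting.
#' @export
nodewise_age_effects <- function(scores, phenotypes, k = 3L, alpha = 0.05,
                                 grid_length = 50L, random_intercept = TRUE) {
  scores <- as.matrix(scores)
  n_nodes <- ncol(scores)
  grid <- seq(min(phenotypes$age), max(phenotypes$age),
              length.out = grid_length)
  newdata <- data.frame(
    age = grid,
    sex = mean(phenotypes$sex),
    motion = mean(phenotypes$motion),
    subject = factor(phenotypes$subject_id[1],
                     levels = unique(phenotypes$subject_id))
  )
  eff <- data.frame(node = seq_len(n_nodes) - 1L,
                    delta_adj_r2 = NA_real_, p = NA_real_,
                    significant = NA)
  traj <- matrix(NA_real_, grid_length, n_nodes)
  for (j in seq_len(n_nodes)) {
    res <- tryCatch(
      delta_adj_r2(scores[, j], phenotypes, k = k,
                   random_intercept = random_intercept),
      error = function(e) NULL)
    if (is.null(res)) next
    eff$delta_adj_r2[j] <- res$delta_adj_r2
    eff$p[j] <- res$p
    if (!is.null(res$full)) {
      traj[, j] <- stats::predict(
        res$full$fit, newdata = newdata,
        exclude = if (random_intercept) "s(subject)" else NULL,
        newdata.guaranteed = TRUE)
    } else {
      traj[, j] <- mean(scores[, j])
    }
  }
  eff$significant <- !is.na(eff$p) & eff$p < alpha / n_nodes
  structure(list(effects = eff, trajectories = traj, age_grid = grid,
                 alpha = alpha, n_tests = n_nodes),
            class = "age_effect_map")
}

#' @export
print.age_effect_map <- function(x, ...) {
  cat(sprintf(
    "age_effect_map: %d nodes, %d significant at Bonferroni %g\n",
    x$n_tests, sum(x$effects$significant, na.rm = TRUE), x$alpha))
  invisible(x)
}
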