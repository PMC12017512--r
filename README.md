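# msgrad

Multiscale structural connectome gradients and their developmental
trajectories, in R.

## The problem

Between ages 6 and 14 the cortex reorganizes across scales — white-matter
tracts mature, intracortical myelin grows, synapses are pruned — and the
question is how the *organization* of structural connectivity changes:
does the principal axis separating primary sensory from transmodal
association cortex sharpen, and does that sharpening track function,
morphology, cognition, and gene expression?

`msgrad` implements the full analysis for researchers working with
parcellated multimodal imaging features:

* **Multiscale fusion** — geodesic distance (GD), microstructural profile
  covariance (MPC, partial correlations of cortical depth profiles
  controlling for the cortex-mean profile), and tract strength (TS, log
  streamline counts) are rank-normalized to a common range, concatenated
  per node, and turned into a normalized-angle affinity
  `1 − arccos(cos θᵢⱼ)/π`.
* **Gradients** — diffusion-map embedding (`D^−α W D^−α`, α = 0.5, Markov
  normalization, components scaled by λ/(1−λ)), age-bin group templates,
  and Procrustes alignment of individual embeddings.
* **Descriptors** — range, SD, explanation ratio per gradient; dispersion
  and eccentricity in the 2-D space of gradients 1 and 3; community
  summaries; participation coefficients `1 − Σₛ(k_is/k_i)²`.
* **Age effects** — penalized-spline mixed models
  `y ~ s(age, k = 3) + sex + motion + (1 | subject)` via `mgcv`, with the
  signed ΔAdj R² (full minus age-free model, signed by the linear age
  coefficient) as effect size and Bonferroni-corrected node maps.
* **Spatial inference** — variogram-matched surrogate maps (permute,
  kernel-smooth at candidate scales, affine variogram match) for
  autocorrelation-aware correlation tests.
* **Structure–function coupling** — top-10%-per-row FC gradient, nodal
  Spearman coupling of structural and functional profiles.
* **Multivariate inference** — PLSC (`R = YᵀX = USVᵀ`, `Lx = XV`,
  `Ly = YU`) with permutation, bootstrap, and 10×5-fold cross-validation;
  single-response PLSR of effect maps on gene expression with bootstrap-Z
  gene ranking and surrogate-corrected enrichment (GMT gene sets).
* **Synthetic cohort** — an accelerated-longitudinal generator with a
  planted, age-scaled primary-vs-transmodal contrast, so every stage is
  testable against known ground truth.

## Worked example

```r
library(msgrad)

parcels <- make_parcels(100, n_communities = 4)
truth   <- planted_truth(parcels, age_slope = 0.05)
cohort  <- simulate_cohort(parcels, truth, n_subjects = 100, seed = 1)

cg <- cohort_gradients(cohort, orient_to = truth$contrast_vector)
cg$templates$overall
#> gradient_set: 100 nodes x 10 components (alpha = 0.5)
#>   explanation ratio: 0.426 0.189 0.189 0.056 0.034 ...

# the fused principal gradient recovers the planted axis
mean(sapply(cg$gradients, function(g)
  cor(g$components[, 1], truth$contrast_vector)))
#> [1] 0.9794729

# gradient-space dispersion increases with age
disp <- sapply(cg$gradients, function(g) dispersion(gradient_space(g)))
delta_adj_r2(disp, cohort$phenotypes)[c("delta_adj_r2", "p")]
#> $delta_adj_r2
#> [1] 0.06506535
#>
#> $p
#> [1] 0
```

The explanation ratio says gradient 1 carries ~43% of the retained
connectivity variance; the correlation of 0.98 shows the embedding
recovers the planted sensorimotor–association axis; the positive
ΔAdj R² (smooth-term p below numerical precision) is the planted
expansion of the gradient space detected by the spline mixed model.

`run_pipeline(default_config(), "out/")` executes every stage
(simulation → preparation → gradients → metrics → age effects → spatial
nulls → coupling → PLSC → PLSR) and writes per-stage TSV/JSON outputs
plus a `manifest.json` with the configuration, seed, and file hashes;
reruns with the same configuration are numerically identical.

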