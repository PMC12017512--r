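---
title: "Multiscale structural gradients: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale structural gradients: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgrad)
```

## The model

Cortical structural connectivity spans scales: long-range white-matter
tracts (tract strength, TS, from tractography streamline counts), spatial
proximity along the cortical sheet (geodesic distance, GD), and
microstructural similarity between regions (microstructural profile
covariance, MPC, from depth-wise intensity profiles).  `msgrad` fuses the
three into a single node-wise connectivity profile and asks how the
low-dimensional organization of that profile — its *gradients* — changes
across late childhood.

The processing chain is:

1. **Feature preparation.**  MPC is the partial Pearson correlation of two
   nodes' depth profiles controlling for the cortex-mean profile,
   thresholded at zero and Fisher-transformed
   (`r -> ln((1+r)/(1-r))`).  TS is `ln(1 + count)` on nonzero entries.
   GD is inverted so proximity maps to affinity.  Each matrix's nonzero
   entries are replaced by average-tie ranks and min-max rescaled to
   `[0, 1]`, which makes the three features commensurate and insensitive
   to monotone distortions of their native scales.
2. **Fusion and embedding.**  Each node's profile is the concatenation of
   its three feature rows (length `3N`).  Pairwise affinity is the
   normalized angle `1 - arccos(cos_sim)/pi`; the affinity is embedded by
   a diffusion map with anisotropy `alpha = 0.5` and automatic-time
   component scaling `lambda/(1 - lambda)`.  Component 1 is the
   primary-to-transmodal (sensorimotor-association) axis; component 3
   typically carries an anterior-posterior pattern in cortical data, and
   the two together span the 2-D "gradient space".
3. **Templates and alignment.**  Diffusion-map components are defined only
   up to sign and rotation across individuals.  Scans are pooled into six
   age bins (6-7, 8, 9, 10, 11, 12-13 years); each bin's mean feature
   matrices give a bin template, every bin template is Procrustes-aligned
   (rotation + reflection, no scaling) to the all-scan template, and each
   individual embedding is aligned to its bin template.
4. **Descriptors.**  Per component: range, population SD, explanation
   ratio (eigenvalue over the summed retained eigenvalues).  In the 2-D
   space: dispersion (summed node distance to the centroid) and per-node
   eccentricity relative to the all-scan template centroid.
5. **Age modeling.**  Every descriptor or node score is modeled as
   `y ~ s(age, k = 3, cubic regression spline) + sex + motion +
   (1 | subject)`, fitted by REML with `mgcv` (`bam` with
   `discrete = TRUE` when the random intercept is present).  The effect
   size is the signed change in adjusted R-squared between this model and
   the same model without the age smooth, signed by the age coefficient of
   the equivalent linear model; node-wise maps are Bonferroni-corrected.
6. **Spatial inference.**  Correlations between cortical maps are tested
   against variogram-matched surrogates: each surrogate permutes the map,
   smooths it with an exponential k-nearest-neighbor kernel at candidate
   scales (5, 10, 20, 40% of nodes), and applies the affine rescaling
   whose variogram best matches the source map's; the p-value is the
   add-one-corrected fraction of surrogate correlations at least as
   extreme as the observed one (two-sided by default, one-sided
   available).
7. **Structure-function coupling.**  FC rows are thresholded to their top
   10% of edges, embedded the same way to give the functional gradient;
   per-node coupling is the Spearman correlation of the fused structural
   affinity row with the FC row; specialization is indexed by the
   participation coefficient `1 - sum_s (k_is/k_i)^2` over communities.
8. **Multivariate inference.**  Brain-behavior association uses PLSC: SVD
   of the z-scored cross-covariance `R = t(Y) X`, composite scores
   `Lx = X V`, `Ly = Y U`, component-wise permutation of the behavior
   rows, bootstrap stability of loadings, and 10 x 5-fold
   cross-validation of the held-out composite correlation.
   Transcriptomic association uses single-response PLSR (NIPALS) of an
   effect map on a region-by-gene matrix, bootstrap Z scores for gene
   weights (weight over bootstrap SD, sign-aligned per resample), top-10%
   positive and negative gene lists, hypergeometric over-representation
   with BH correction, and a surrogate-map null that repeats the whole
   PLSR-plus-selection procedure on variogram-matched maps.

## What the synthetic cohort emulates

Real multimodal developmental imaging is not desk-available, so the
package ships a generator whose defaults define the study conditions used
throughout the tests:

* **Parcellation.**  `make_parcels()` places nodes on a unit sphere
  (Fibonacci spiral), with hemispheres split by x-sign and communities as
  contiguous latitude bands — a stand-in for functional communities that
  preserves what the spatial statistics need: a genuine metric space with
  smooth maps on it.
* **Planted axis.**  The ground-truth contrast is the standardized
  latitude, entering every scan's depth profiles with amplitude
  `1 + age * age_slope + u_subject` (`age_slope = 0.05`/year by default,
  subject intercept SD 0.15).  MPC similarity is therefore higher within
  each end of the contrast, and the fused principal gradient recovers the
  planted axis (|r| > 0.9 at default noise).
* **Features.**  GD is great-circle distance plus small positive jitter;
  streamline counts are negative-binomial with an exponential distance
  decay (`ts_scale * exp(-d / 0.75)`, dispersion 4) and a within-community
  bonus, reproducing sparse, skewed, distance-dependent count matrices;
  FC is a correlation matrix built from the fused structural affinity
  plus community block signal and noise; behavior scores are linear in
  the subject's realized contrast amplitude.
* **Design.**  Subjects receive 1-3 scans with mixing proportions
  159:83:39 (an accelerated-longitudinal design), first-scan ages uniform
  on 6-14 years and within-subject increments of 0.5-1.5 years.  The
  default cohort size is 100 subjects (~160 scans).  This size matters:
  with substantially fewer scans the per-bin templates are noisy enough
  that bin-wise alignment induces bin-level correlation in the 2-D-space
  descriptors and inflates the age-model false-positive rate; at the
  default size the null calibration is nominal.
* **Genes.**  Signal genes are the planted effect map at loading 0.8 plus
  spatially autocorrelated noise; null genes are pure autocorrelated
  noise with kernel range 0.2 radians.  The range is deliberately small
  enough that a null gene's chance correlation with a smooth target map
  stays modest (mean |r| about 0.16 at 100 nodes); much smoother gene
  fields make signal and null genes information-theoretically hard to
  separate regardless of method.

What the generator does *not* emulate: cortical mesh geometry,
hemodynamics, realistic tractography biases (gyral bias, false
positives), scanner or site effects, and any quantitative effect sizes of
a real cohort — the planted magnitudes are free parameters of the
artifact.  Passing tests therefore certify the machinery (oracle
equivalence, calibration, recovery under known truth), not empirical
claims about any particular dataset.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 | diffusion-map anisotropy; 0.5 normalizes the density of the affinity graph |
| `n_components` | 10 | retained embedding components |
| age bins | 6-7, 8, 9, 10, 11, 12-13 | template groups (years) |
| `k` | 3 | maximum basis complexity of the age spline |
| FC threshold | 0.10 | per-row fraction of retained FC edges |
| `n_surrogates` | 1,000 | surrogate maps per inference |
| `n_perm`, `n_boot` | 1,000 | PLSC/PLSR resampling counts |
| variogram bins | 25 | equal-count distance bins, pairs below the 70th distance percentile |
| smoothing scales | 5/10/20/40% | candidate k-NN neighborhood fractions for surrogates |
| top gene fraction | 0.10 | per-tail PLS1 gene selection |

## Numerical and design choices

* **Inverted GD** is realized in rank space (`1 - rescaled rank`), not as
  `1/d`: rank-space inversion is scale-free and lands all three features
  on the same `[0, 1]` range by construction.
* **MPC log transform.**  The zero-thresholded partial correlations are
  mapped through the Fisher form `ln((1+r)/(1-r))`, which is finite at
  `r = 0`, monotone, and clipped at `r = 1 - 1e-12`; `ln(1 + r)` is
  available behind `mpc_transform = "log"`.  Because the subsequent rank
  normalization is invariant to monotone maps, the choice does not affect
  the fused gradients.
* **Tie handling** in rank normalization uses average ranks on the upper
  triangle mirrored to the lower, keeping matrices symmetric by
  construction.
* **Diffusion time** is handled by the `lambda/(1-lambda)` scaling; raw
  Markov eigenvalues are reported and explanation ratios are computed
  over the retained components.
* **Degenerate inputs** have defined behavior: zero-variance profiles
  zero their MPC row with a warning; all-tied feature values map to 0.5;
  zero-variance responses short-circuit to a zero age effect with p = 1;
  constant coupling profiles are recorded as missing; disconnected
  affinity graphs are an error naming the components.
* **Template hierarchy.**  Whether bin templates should themselves be
  aligned to an all-scan template before individual alignment is an open
  design point; the package does align them, which makes descriptors
  comparable across bins and is required for the template-centroid
  eccentricity to be meaningful.
* **Sign orientation.**  After alignment the global sign of each
  component is still arbitrary; `orient_gradients()` fixes component
  signs against a reference map (in simulations, the planted contrast;
  with real data, any primary-region proxy).
* **Surrogate sidedness.**  The surrogate correlation test defaults to
  two-sided with an add-one continuity correction; one-sided variants are
  exposed because signed hypotheses differ across analyses.
* **PLSC conventions.**  Columns of X and Y are z-scored before the
  cross-covariance; permutation compares singular values component-wise
  without realignment; bootstrap saliences are sign-aligned to the
  original by cosine.  Behavior variables where larger means worse
  (response times) are not re-signed; interpretation is left to the
  loadings.
* **Age-effect estimand.**  In an accelerated-longitudinal design the
  reduced model's subject intercepts absorb whatever part of the age
  signal varies only between subjects, so the mixed-model delta adjusted
  R-squared is intrinsically attenuated relative to the marginal variance
  share of age.  Parameter-recovery experiments that target a known
  variance share therefore use the cross-sectional mode
  (`random_intercept = FALSE`, one scan per subject), where the estimand
  equals the planted share; the longitudinal mixed mode is validated for
  calibration (uniform null p, no inflation from subject offsets), which
  is the property that matters for the significance maps.
* **Smooth-term p-values** are the standard approximate Wald test on the
  penalized spline coefficients.  With an estimated random-intercept
  variance in the model this approximation is known to be very slightly
  anticonservative in large simulations (type-I about 0.06 at
  nominal 0.05 in our checks); Bonferroni-corrected maps are essentially
  unaffected, but exact tail behavior should not be over-interpreted.
* **In-sample PLSR explained variance** grows mechanically like
  `p/(n + p)` under independence once genes outnumber regions; reported
  component-1 explained variance is an in-sample quantity and should be
  read against that baseline, not against zero.

## Problem sizes used by the tests

The bundled tests and the acceptance script run the full pipeline at
100 nodes, 100 subjects (~160 scans), 500 genes with 50 signal genes,
100-500 surrogates and 200-1,000 resamples per inference — sizes chosen
so each statistical property (calibration bands, recovery targets) is
measured with adequate Monte-Carlo precision while a complete run stays
inside a coffee break on one core.  Production inference on real data
should raise all resampling counts to 1,000.

## Known limitations

* The variogram-matching surrogates approximate, not reproduce, the full
  spatial covariance; calibration was verified for exponential-kernel
  fields at ranges 0.3-0.75 radians on the sphere.
* The enrichment surrogate null inherits the smoothness of the effect
  map: for extremely smooth maps (near-harmonic patterns) surrogate maps
  legitimately regenerate similar top-gene lists and the test is
  conservative by design.
* No vertex-level embedding, no spin-rotation nulls, no multi-response
  PLSR, and no automatic spline-complexity selection.
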