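---
title: "Whole-brain signature modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain signature modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(brainsig)
```

## The problem

During the anticipation of an uncertain aversive event — the classic
threat-of-shock situation — people report graded levels of anxious
arousal. A *signature* model asks whether a single, fixed multivariate
pattern of brain activity tracks those subjective reports across trials,
people and studies: a voxel weight map $w$ plus intercept $b$ such that for
any vectorized activation map $x$ the *signature response*
$\hat y = w^\top x + b$ predicts the reported rating. brainsig implements
the full workflow for developing and stress-testing such signatures, and a
synthetic-data generator with known ground truth so that every stage can be
validated quantitatively — something real data can never offer, because the
true generating pattern of real data is unknown.

## The model pipeline

1. **First-level GLM.** Each anticipation epoch is modelled as a boxcar
   convolved with the canonical double-gamma HRF (peak delay 6 s,
   undershoot delay 16 s, dispersions 1, peak:undershoot ratio 6, 32 s
   kernel — the field's standard parameterization; the source analyses name
   the kernel but not its parameters). Designs are built per rating level
   (one regressor per observed 1–5 rating of no-shock anticipations,
   separate no-interest regressors for shock-followed anticipations,
   outcome/rating epochs and dummy trials) or per trial (beta series).
   Estimation is plain OLS on run-concatenated data with per-run
   intercepts; rank deficiency is an error naming the collinear columns,
   never a silent pseudo-inverse.
2. **Signature training.** Linear $\varepsilon$-SVR with fixed $C = 1$ and
   $\varepsilon = 0.1$ on gray-matter-masked rating-level maps (one map per
   rating a participant actually used — typically 3–5). Only no-shock
   trials contribute, so the model reflects anticipatory state rather than
   shock responses.
3. **Evaluation.** 10×10-fold cross-validation grouped by participant
   (all of a participant's maps share a fold; leakage is checked by an
   internal assertion), per-map predictions averaged over the ten repeats.
   Metrics: overall prediction–outcome Pearson r, explained variance score
   $\mathrm{EVS} = 1 - \overline{(y-\hat y)^2}/\overline{(y-\bar y)^2}$,
   within-participant correlations averaged after Fisher r-to-z, label
   permutation tests (5000 shuffles at full scale), two-alternative
   forced-choice on high (ratings 4–5) versus low (1–2) average maps with
   Cohen's d and an exact two-sided binomial test, participant-resampling
   bootstrap of the weight map ($z = \mathrm{mean}/\mathrm{sd}$ per voxel,
   thresholded at uncorrected $p<.001$ / $p<.01$).
4. **Interpretation.** Within-individual SVR models per participant,
   transformed to forward encoding maps via the Haufe structure
   coefficients, and a conjunction ("core system") of voxels whose decoder
   weights *and* encoding coefficients are jointly positive and significant
   (one-sample t-tests, BH-FDR $q<.05$, one-sided).
5. **Comparison.** Cross-application of a signature to other cohorts,
   permutation tests of correlation differences, spatial correlation of
   weight maps (optionally restricted to bootstrap-surviving voxels),
   ROI cosine profiles, ROI-restricted retraining and random
   voxel-subsampling curves.

## The synthetic cohort generator

`synth_spec()` + `simulate_cohort()` emulate an uncertainty-varying
threat-anticipation study: 4 runs of 5 anticipation trials in each of four
cue conditions (certain safety, low/medium/high shock uncertainty), cue
durations 6–10 s, a 1–5 anxious-arousal rating after each anticipation,
and shocks after 60% of uncertain-threat trials. Per trial the activation
vector is

$$x_t = a \cdot g_p \cdot r_t \cdot u \;+\; c_{\mathrm{ar}} \cdot z_t \cdot
u_{\mathrm{ar}} \;+\; c_{\mathrm{vis}} \cdot k_t \cdot u_{\mathrm{vis}}
\;+\; \epsilon_t,$$

with $u$ a unit-norm multi-blob "anxiety" pattern, $g_p$ a log-normal
participant gain, $r_t$ the realized (rounded, clipped) rating,
$u_{\mathrm{ar}}$ an autonomic-arousal-like confound whose amplitude $z_t$
correlates with the ratings through a shared latent Gaussian (so
specificity analyses have a tunable partially-correlated competitor),
$u_{\mathrm{vis}}$ a visual cue pattern scaling with the condition, and
$\epsilon_t$ white Gaussian noise smoothed with an 8-mm-FWHM kernel and
rescaled to a per-voxel SD, emulating smoothed fMRI residuals. Ratings are
drawn Gaussian around nondecreasing condition means (default 1.2, 2.4,
3.3, 4.3 across safety → high) and rounded to 1–5, which reproduces the
partial coverage of the scale seen empirically (3–5 rating-level maps per
participant). An optional BOLD-level mode convolves the trial betas with
the HRF and adds AR(1) noise and drift, closing the loop through the GLM.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `signal_amplitude` | 0.1 beta units / rating unit | sets the absolute beta scale small relative to the fixed SVR cost $C=1$; this is the well-regularized regime for a fixed-hyperparameter SVR (see below) |
| `noise_sd` | 0.04 beta units | per-voxel single-trial SNR ≈ 0.6: individual voxels are weakly informative, so prediction must pool across the pattern — the regime multivariate decoding targets |
| `gain_log_sd` | 0.3 | between-participant amplitude heterogeneity; produces realistic cross-validated r ≈ 0.64–0.82 rather than ceiling performance |
| `smoothing_fwhm` | 8 mm | matches standard preprocessing smoothness |
| `shock_probability` | 0 / .6 / .6 / .6 | the reference paradigm's predetermined rate |
| mask | 912-voxel sphere, 2 mm voxels | desk-scale stand-in for a gray-matter mask; all geometry checks are exact, no implicit resampling |

A design-phase sweep showed a structural property worth recording: when
map magnitudes are large relative to $C$, most training maps become
bound support vectors and each injects its full noise vector into the
weight map — raw weights then correlate poorly with the generating
pattern (cosine ≈ 0.2) even at high SNR. This is the regime real
whole-brain data live in, and it is exactly why the published workflow
interprets bootstrap-thresholded and Haufe-transformed maps rather than
raw weights. The default beta scale keeps the synthetic cohort in the
well-regularized regime where raw-weight recovery is also good
(cosine ≈ 0.8), so both recovery and inferential machinery can be tested.

### What the generator does *not* emulate

Physiological and motion artifacts beyond AR(1)+drift, EPI distortion,
between-region correlation structure of real resting activity, nonlinear
HRF variation, and real anatomical geometry. Passing tests therefore
demonstrate correctness of the estimation machinery and calibration of the
inference under the stated generative model — not that any real dataset
satisfies that model.

## Numerical and design choices

- **Voxel order.** Vectorization uses ascending linear index in R's native
  column-major array layout; 1-based indices; the order is frozen and
  bit-reproducible. Grids must match exactly (affine tolerance $10^{-4}$
  mm); resampling is never implicit.
- **SVR engine.** libsvm (via e1071) with convergence tolerance $10^{-10}$;
  the test suite checks the trained weights against an exhaustive
  KKT-enumeration solution of the dual on all small problems to $10^{-6}$.
  The intercept of an $\varepsilon$-SVR can be non-unique (a flat interval)
  when no free support vector pins it; weight uniqueness is guaranteed by
  the strictly convex $\|w\|^2$ term, so oracle comparisons are on weights.
- **Feature scaling** is off by default — published signature responses are
  plain dot products on raw beta maps. A z-scoring option estimates
  parameters on training folds only and folds them back into $(w, b)$, so
  application remains a dot product either way.
- **Scale covariance.** Scaling all maps by $k$ is dual-equivalent to
  rescaling the cost to $C/k^2$ (weights scale as $1/k$); with $C$ held
  fixed, the map scale acts as an effective regularization knob (tested).
- **EVS definition.** $1 - \overline{(y - \hat y)^2} / \overline{(y - \bar
  y)^2}$: 1 for perfect prediction, 0 for the constant-mean predictor,
  negative below that. The residual is not re-centred, so a constant bias
  costs EVS but not r.
- **Haufe transform.** $A = \mathrm{cov}(X)\,W\,\mathrm{cov}(W^\top X)^{-1}$,
  computed voxelwise as $\mathrm{cov}(x_v,\hat y)/\mathrm{Var}(\hat y)$
  with trial-centred columns and unbiased ($n-1$) covariances. Because a
  backward model's overall scale is arbitrary, $W$ is normalized to unit
  length before the latent is formed; $A$ is then invariant to positive
  rescaling of $W$. Centring is per concatenated trial set (not per run).
- **Permutation p-values** use the add-one convention
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$,
  never exactly zero.
- **Δr permutation scheme.** The correlation-difference test is named but
  not specified in the source analyses. Here the null jointly permutes the
  response rows — the same permutation inside both correlations when the
  two sets are matched (so identical targets give a degenerate null and
  p = 1); unmatched sets (cross-cohort application) are permuted
  independently. This is a documented interpretation, not an assertion of
  the original implementation.
- **Forced choice** scores ties as 0.5 (unbiased under the null); ties are
  excluded from the exact binomial count.
- **Bootstrap weight maps** convert $z$ to p through the normal
  approximation; replicates that lose the second rating level are redrawn
  so the replicate count stays fixed.
- **ROI contribution rule.** The "relative contribution" of several models
  to an ROI is ambiguous in the source figure caption; here each in-ROI
  voxel is assigned to the model with the largest absolute thresholded
  weight (ties split equally), and contributions are the assigned voxel
  fractions — a documented interpretation.
- **Spatial-correlation nulls** shuffle voxels without preserving spatial
  smoothness; a smoothness-preserving null would be less liberal and is a
  known limitation.
- **Dummy-trial regressors** can be grouped or split fast/slow via the
  events table's `trial_type`; the source description does not fix this
  choice.
- **Gray-matter mask provenance** (probability threshold vs binary atlas)
  is likewise not fixed upstream; any user-supplied binary mask is
  accepted.

## Problem sizes used in the shipped tests

The test-suite and the reproduction script run entirely on synthetic
cohorts sized for a laptop: the default recovery cohort is 30 participants
× ~44 no-shock trials on a 912-voxel spherical mask; null calibration uses
150–250 small null cohorts with 500-shuffle permutation tests; the
specificity analysis uses two 12-participant cohorts with disjoint-support
patterns; the subsystem analysis uses 24 participants on a 2176-voxel mask
with a 3-blob ground truth — chosen by a power check so that the
distributed-beats-local comparison is reliably expressed rather than lost
in cross-validation noise. Full-scale settings (5000 permutations and
bootstrap iterations) remain the documented defaults of the corresponding
functions.

## Known limitations

- The pipeline assumes maps already share a common grid; spatial
  normalization, smoothing and resampling happen upstream.
- OLS without prewhitening is used for beta estimation; betas feed a
  cross-validated decoder, where unmodelled autocorrelation inflates no
  test statistic, but GLM residual variances should not be reused for
  parametric inference.
- The generator's confound patterns are spatially fixed per cohort;
  real nuisance processes drift.
- Forced-choice ROC curves are computed from the paired responses, not
  from an independent test set.
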