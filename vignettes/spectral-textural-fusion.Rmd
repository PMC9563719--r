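---
title: "Spectral-textural data fusion for hyperspectral starch prediction"
author: "starchfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-textural data fusion for hyperspectral starch prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Starch content (g per 100 g fresh weight) is a primary quality attribute of
potato tubers, conventionally measured by destructive enzymatic assay.
Visible/near-infrared hyperspectral imaging offers a non-destructive
alternative: a line-scan camera records a reflectance *hypercube* — two
spatial axes by 428 wavelengths spanning 382–1004 nm — from which both
chemistry (the spectrum) and surface structure (image texture) can be read.

`starchfusion` implements the complete chemometric pipeline for predicting
starch from such cubes, and in particular the *data-fusion* question: does
combining spectral and textural information predict better than either
block alone, and does it matter whether the blocks are fused wholesale
(low-level) or after per-block variable selection (mid-level)?

## Pipeline and models

The stages, each an exported function:

1. **Calibration** (`calibrateReflectance`): two-point correction
   $R = (I_{raw} - I_{dark}) / (I_{white} - I_{dark})$. Dead reference
   pixels (white = dark) are zeroed and counted rather than raised as
   errors, because real reference cubes contain dead pixels.
2. **ROI spectra** (`extractROI`, `meanSpectrum`): a fixed, axis-aligned
   100 × 100-pixel region of interest, centred by default
   (0-based start `floor((dim - size)/2)`, half-open indexing); the mean
   over its pixels is the sample spectrum. No tuber segmentation is
   attempted — the ROI convention mirrors the fixed-window practice of
   interactive hyperspectral software.
3. **SNV** (`snv`): each spectrum is centred and divided by its own
   standard deviation (the chemometric convention with the $n-1$
   denominator), removing additive offsets and multiplicative scatter.
4. **PC score images** (`pcaScoreImages`): PCA *per sample* over the ROI
   pixels (pixels are observations, bands are variables), keeping the
   first three score images. Loadings are oriented so their
   largest-magnitude element is positive, which stabilises score-image
   sign across samples; cross-sample comparability is otherwise limited,
   which is acceptable because only within-image texture statistics are
   consumed downstream. The decomposition uses the eigendecomposition of
   the 428 × 428 pixel covariance rather than a direct SVD of the
   10^4 × 428 pixel matrix: for reflectance data of magnitude ~1 the two
   are numerically equivalent, and the covariance route is much faster
   when 96 cubes are processed repeatedly.
5. **GLCM texture** (`glcm`, `glcmFeatures`, `textureVector`): each score
   image is min–max quantized to 64 gray levels (a common GLCM default
   balancing sparsity and discriminability), and symmetric, normalised
   co-occurrence matrices are computed at distance 1 in the four
   directions 0°, 45°, 90°, 135°. Four statistics — correlation, contrast,
   entropy (base-2 logarithm, so in bits) and uniformity (angular second
   moment $\sum p_{ij}^2$) — are averaged over directions, giving 12
   features per sample. Degenerate GLCMs (zero marginal variance) define
   correlation as 0 to keep NaNs out of selection.
6. **Variable selection** (`carsSelect`, `correlationSelect`):
   competitive adaptive reweighted sampling shrinks the wavelength set
   over N = 50 Monte-Carlo runs. Each run fits a PLS model on 80% of the
   samples, weights variables by normalised absolute coefficients,
   enforces the exponentially decreasing retention schedule
   $r_i = a e^{-k i}$ (anchored at $r_1 = 1$, $r_N = 2/p$), resamples the
   retained set by weight, and scores the subset by 5-fold RMSECV; the
   subset with minimum RMSECV wins. Because the reweighted draw is
   specified *without replacement at the same count*, it permutes rather
   than thins the enforced top-$k$ set, so the shrinkage is driven by the
   EDF schedule — a deliberate, reproducible simplification of the
   original with-replacement sampling. Texture variables are selected by
   Pearson correlation with starch, strict $|r| > 0.3$.
7. **Fusion** (`fuseLow`, `fuseMid`): column concatenation of all
   428 + 12 variables (low-level) or of the selected wavelengths plus
   selected texture features (mid-level). Mid-level width is
   data-dependent, not fixed.
8. **PLSR** (`plsFit`, `selectLvCV`, `evaluateModel`): univariate NIPALS
   partial least squares. Predictors are autoscaled — not merely centred —
   in every model because fused blocks mix reflectance and texture
   statistics of incommensurate scale; the response is centred only. The
   latent-variable count is chosen by 5-fold cross-validation up to 15,
   folds being contiguous blocks of a seeded shuffle, taking the smallest
   count within 1e-10 of the minimum RMSECV.
9. **Split and metrics** (`rankOrderSplit`): samples are sorted by starch,
   the middle of each consecutive triplet goes to the prediction set
   (64/32 for 96 samples; prediction range nested inside calibration
   range). Models report Rc/RMSEC on calibration, Rp/RMSEP on prediction,
   and RPD = SD(prediction-set reference)/RMSEP with the $n-1$ SD; RPD
   above 2 is the usual screening threshold.

Variable selection runs on the calibration set only, so the prediction set
never influences which variables enter the mid-level model. CARS operates
on the SNV-treated spectra, which is the stronger single-spectral block.

`runPipeline()` chains everything and emits the five-model comparison (raw
spectra, SNV spectra, texture, low-level fusion, mid-level fusion) plus a
run log recording every convention listed above.

## The synthetic data generator

No hyperspectral potato images are publicly deposited, so the package
ships a first-class generator (`simConfig`, `simulateDataset`) that plants
exactly the statistical structure the analysis assumes, making the whole
pipeline testable end to end:

* **Reference values**: truncated normals per variety — 68 samples at
  10.23 ± 2.95 g/100 g bounded to [1.77, 18.31], and 28 samples at
  18.96 ± 1.29 bounded to [17.01, 22.81] — drawn by rejection sampling
  (exact at these sizes).
* **Spectra**: a fixed tilted baseline (mean 0.55, linear + quadratic
  shape across the grid) minus Gaussian absorption dips (SD 15 nm) at
  410, 680 and 980 nm whose depths grow affinely with starch
  ($d = 0.006\,(o_c + s)$, offsets 15/18/22). The fixed baseline shape is
  essential: with a flat baseline the dips would dominate each spectrum's
  own SD and SNV would normalise the starch signal away. Per-sample
  multiplicative (SD 0.12) and additive (SD 0.05) scatter make raw
  spectra worse than SNV-treated ones; per-peak depth noise (SD 0.025)
  represents chemistry not explained by starch and sets the attainable
  spectral accuracy; band noise (SD 0.012) emulates the burr-like
  instrument noise of real line-scan spectra and discourages tiny
  wavelength subsets.
* **Cubes**: every pixel carries the sample spectrum modulated by a
  coarse multiplicative illumination field (PC1), plus a texture
  component along a fixed spectral direction (Gaussian bump at 850 nm)
  that becomes PC2. That component mixes a smooth Gaussian-filtered
  noise field, whose correlation length shrinks with starch
  (grain $= \max(1.5, 7 - 0.2\,s)$), with sparse speckles whose
  amplitude decays with starch ($1.5\,e^{-s/5}$, capped so speckles never
  clip the reflectance range). Low-starch images are speckle-dominated —
  the bulk of pixels collapses into few quantization levels, so GLCM
  uniformity is high and GLCM correlation low; high-starch images are
  smooth-field dominated with the opposite signature. Lognormal
  per-sample jitter on grain (SD 0.7) and speckle amplitude (SD 1.0)
  keeps the texture–starch correlations moderate: across samples the
  planted pattern is $r(\mathrm{correlation\_PC2}) \approx +0.6$ and
  $r(\mathrm{uniformity\_PC2}) \approx -0.6$, matching the sign pattern
  (largest positive / largest negative) the analysis is designed to
  exploit.

Per-sample seeds are derived as base seed + sample index, so any single
cube is reproducible without regenerating the set. What the generator does
**not** emulate: instrument optics, specular glare, tuber shape and
background (no masking is needed because cubes are texture-stationary),
spatial chemical gradients within a tuber, and wavelength-dependent noise.
Passing tests therefore demonstrate that the pipeline recovers planted
structure of this kind — not that it attains any particular accuracy on
real potatoes.

## Numerical conventions and degenerate inputs

* SNV refuses constant spectra by sample name; GLCM correlation of a
  degenerate matrix is 0; constant images quantize to level 0 and have
  uniformity exactly 1.
* `quantizeImage` maps min–max linearly with `floor`, maximum to the top
  level, and is invariant to positive affine transforms.
* CARS never retains fewer than 2 variables; weights that sum to zero
  fall back to uniform.
* `plsFit` stops early if a deflated response loses all covariance with
  the predictors; zero-variance predictor columns get unit scale and so
  carry no information instead of producing NaNs.
* `selectLvCV` truncates an infeasible latent-variable ceiling with a
  warning; ties resolve to the smallest count.
* In the rank-order split, ties in starch are broken by input order, so
  splits are deterministic.

## Problem sizes used by the test-suite

Unit tests run on miniature fixtures (8 × 8 images, 20 × 8 regression
problems, 2 × 2 × 3 cubes). End-to-end checks use the full default study
design — 96 samples, 120 × 120 × 428 cubes, 100 × 100 ROI — across five
seeds for the fusion comparison and across 20 repetitions (n = 60,
p = 100) for the CARS recovery experiment; these sizes are the package's
chosen compromise between statistical resolution and a test suite that
runs in minutes.

## Known limitations

* Per-sample PCA means loadings are not comparable across samples beyond
  the sign convention; only texture statistics of the score images are
  comparable. A pooled-PCA variant would be a natural extension.
* The reweighted-sampling step of CARS is membership-neutral (see above);
  selection pressure comes from the enforced schedule and the
  minimum-RMSECV pick.
* The latent-variable argmin can wander up the flat tail of an RMSECV
  curve on near-noiseless data; a one-standard-error rule would be more
  parsimonious but is deliberately not applied.
* Only SNV preprocessing is provided; derivative/MSC preprocessing and
  alternative selectors (SPA, UVE, GA) or regressors (SVR, forests) are
  out of scope.
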