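---
title: "Methods: multi-dimensional UAV features for potato biomass estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-dimensional UAV features for potato biomass estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models, the tunable constants and their defaults, what
the synthetic-trial generator does and does not emulate, and the design
decisions taken where the methodology left choices open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The estimation problem

Aboveground biomass (AGB, g/m²) of a ridge-planted potato crop is to be
estimated per experimental plot from six-band UAV reflectance imagery
(450, 555, 660, 720, 750, 840 nm, values in [0, 1]), a photogrammetric
surface model (DSM) and a terrain model (DEM). The pipeline extracts
four dimensions of candidate predictors per plot — spectral (SV),
texture (TV), geometric (GV) and frequency-domain (FDV), 39 variables
in all — ranks them with three feature-selection algorithms, and
evaluates partial least squares (PLSR) and random-forest (RFR)
regressions on a stage-stratified calibration/validation split.

## 2. Spectral variables: unmixing and soil-free indices

Mixed pixels are decomposed against a stage-specific library of pure
endmember spectra by fully constrained least squares:
minimise ‖R_mp − Σᵢ Abdᵢ Rᵢ‖₂ subject to Abdᵢ ≥ 0 and Σᵢ Abdᵢ = 1.
The solver (C++, `src/fcls.cpp`) is a primal active-set method on the
non-negativity constraints: the equality-constrained subproblem is
solved through its KKT system, infeasible components are driven out of
the support, and zeroed components re-enter when their KKT multiplier
is negative, so the exit point satisfies the full KKT conditions of the
quadratic program. Rank-deficient libraries (e.g. duplicated
endmembers) are solved through the pseudo-inverse — which selects the
minimum-norm abundance among the equal-residual solutions — and flagged
`nonunique`. Tests cross-check the solver against an independent
quadratic-programming routine (`quadprog::solve.QP`) and an exhaustive
simplex-grid search.

Vegetation abundance is the summed abundance of all *non-soil*
endmembers — leaves, yellow leaf and flower alike. The soil-free index
is `VI[v] = VI[plot] × vegetation abundance`. By default abundance maps
are computed per pixel and averaged over the plot ROI (`vi_v_mode =
"pixel"`); unmixing the plot-mean spectrum instead is available behind
`vi_v_mode = "plot"` and agrees closely under linear mixing.

Index formulas are evaluated exactly as defined (see `?compute_vi`);
MTCI uses the (R840 − R720)/(R720 + R660) form. A vanishing denominator
yields `NA`, which downstream correlation and regression steps drop
with a warning rather than raising an error.

## 3. Texture variables

Each plot ROI of each band is min–max quantized to G = 32 gray levels
(configurable), and co-occurrence matrices are accumulated at distance
1 px in three ridge-relative directions: along the ridge (`Dpar`),
across it (`Dperp`) and diagonal (`D45`), symmetrized and normalized.
One GLCM is computed per plot ROI; no sliding window is used, since the
plot is the analysis unit. The six statistics use the standard Haralick
forms (natural-log entropy; see `?glcm_statistics`) — the underlying
methodology names the statistics but not their formulas, so the
community-standard definitions are adopted and documented. The
band/direction pair whose six statistics have the highest mean |Pearson
r| with AGB is selected (`screen_texture_source`), with deterministic
ties broken by band order then direction order.

## 4. Geometric variables

Canopy height is the ROI mean of max(DSM − DEM, 0). FVC comes from the
dimidiate pixel model: the bare-soil and full-vegetation NDVI bounds
are the 1st and 99th scene percentiles ("98 % confidence" read as the
central 98 % of the scene NDVI distribution — standard DPM practice;
bounds are scene-wide because per-plot extremes are unstable at
60×40 px), each pixel's FVC is the clipped linear ramp between them,
and the plot value is the ROI mean. The independent cross-check is a
linear SVM trained on seed pixels taken from the NDVI extremes
(vegetation above the 0.85 quantile, soil below the 0.15 quantile);
FVC is then the classified-vegetation pixel fraction. Any function
mapping an n×6 band matrix to a logical vegetation indicator satisfies
the classifier contract, which is how tests inject oracle classifiers.

## 5. Frequency-domain variables

The six-point spectrum r₁…r₆ (ascending wavelength, 1-based band index
j) is decomposed as A₀/2 = mean(r), Aₜ = (2/n)Σⱼ rⱼcos(2πtj/n),
Bₜ = (2/n)Σⱼ rⱼsin(2πtj/n) for t = 1…6, with amplitude
Cₜ = √(Aₜ² + Bₜ²) and phase φₜ. The phase is computed as the
two-argument arctangent atan2(Aₜ, Bₜ) rather than arctan(Aₜ/Bₜ): B₆ is
identically zero at n = 6 (the t = 6 sine vanishes at integer j), so
the single-argument form is undefined on inputs that necessarily occur;
φₜ is set to 0 where Cₜ ≈ 0. With n = 6 the orders alias
(A₆₋ₜ = Aₜ, B₆₋ₜ = −Bₜ, hence C₅ = C₁, C₄ = C₂, A₆ = 2·A₀/2); all six
orders are still emitted because the screening and the 39-variable
contract operate on the full 25-parameter set. Note that C₆ = 2·mean(r)
under the [0, 1] reflectance invariant, which is why the largest
amplitude typically appears at the sixth order.

## 6. Feature selection

**RReliefF** (regression Relief): features and target are min–max
normalized; every instance is visited (m = n); its k = 10 nearest
neighbours under Manhattan distance, uniformly weighted, accumulate the
probability mass of differing prediction (NdY), differing feature value
(NdF) and both (NdYandF); the weight is W(F) = NdYandF/NdY −
(NdF − NdYandF)/(m − NdY). Constant features receive exactly 0. The
neighbour count, distance and weighting are the algorithm's common
defaults, exposed as arguments.

**RF-Gini**: the Gini index G = 1 − Σp²ᵥ is a classification purity
criterion, so the continuous target is quantile-discretized into 4
classes (empty bins collapse with a warning) and a classification
forest's mean decrease in Gini is reported. A variance-reduction
importance on a regression forest is available behind
`mode = "variance"`; the discretized form is the default because it
evaluates the printed classification criterion.

**RF-OOB**: a regression forest with K = 500 trees is grown with bag
membership recorded; for each feature, the column is permuted once with
a seeded permutation and each tree's out-of-bag MSE is recomputed on
its own OOB samples; the importance is the mean over trees of E₂ − E₁.
Permuting independently within every tree's OOB subset would require
one prediction pass per feature and tree (tens of thousands of passes);
the single per-feature permutation evaluated on per-tree OOB subsets is
the standard reading of the scheme at 1/K the cost. Additive-Gaussian
corruption is available behind `corrupt = "noise"`, and explicit
permutations can be supplied (an identity permutation forces E₂ = E₁
and zero importance, which the tests exploit). Trees with fewer than
two OOB samples contribute zero with a warning.

`select_top` keeps the n = 10 best-ranked features, or all of them when
fewer are available; ties break by the fixed column order of the table.

## 7. Regression and evaluation

The split is random, seeded, stratified by stage, at a 2:1
calibration:validation ratio (the ratio is a package choice; the
methodology shows separate datasets without stating one). Samples are
plot × stage rows pooled across the three stages. PLSR chooses its
latent-component count (≤ 10, and never above the rank of the centred
predictor block — harmonic aliasing makes some columns exactly
collinear) by seeded 10-fold cross-validated RMSE; a numerically
singular fit retries with fewer components and a warning. Predictions
are deliberately not clipped at zero so the characteristic negative
low-AGB PLSR predictions remain observable in the prediction tables.
RFR uses 500 trees. Metrics: R² = 1 − SSres/SStot (prediction R², may
be negative; squared Pearson correlation is used only in screening),
RMSE, MAE, and nRMSE = 100·RMSE/mean(observed). For a constant observed
vector R² is defined as 0.

`run_experiment` evaluates any (combination × selection × regression)
grid: selection is computed on the calibration partition only, within
the combination's features. The seven dimension combinations are all
subsets of {SV, TV, GV, FDV} that contain SV and at least one other
dimension.

## 8. The synthetic-trial generator

The generator emulates the study conditions: a 48-plot factorial trial
(4 varieties × 4 NPK fertilization gradients × 3 repetitions), imaged
at the seedling (SP), flowering (FP) and tuber (TP) stages, on a
480 × 240 px raster of 60 × 40 px plots (8 × 6 grid).

**Endmembers** are parametric templates — a logistic red edge plus
green bump for leaves, a yellow-green template for senescent leaves, a
linear brightness ramp for soil, a bright flat spectrum for flower —
with small seeded per-band jitter. Shaded variants are darker by a
wavelength-dependent factor (0.30 at 450 nm to 0.52 at 840 nm; shadows
are relatively NIR-brighter through canopy scattering). The factor must
not be constant: an exactly proportional shaded spectrum would make the
mixing matrix rank-deficient and abundances unidentifiable, defeating
the unmixing-recovery guarantees.

**Canopy geometry.** Ridges run along image rows with a 30 px period
(≈ 56 cm at the 1.88 cm resolution the sensor model implies). The
vegetated fraction across the ridge is a steep logistic in
cos(2πu/period), with canopy width w = 0.28 + 0.65·v growing with the
plot's fertility response v (fertilization level + variety offset +
noise, clipped to [0.05, 0.95]) and full density at the crest. The
profile steepness (14) and period were chosen so that a binary pixel
classification and the continuous subpixel cover agree to a few
percent — at much sharper edges or shorter periods, pixel sampling
quantizes the classified fraction in steps that no estimator can
bridge.

**Latent structure and AGB.** Canopy vigor is superlinear in canopy
amount, vigor = 0.3·a + 0.7·a² with a the normalized canopy width:
biomass accumulates faster than cover once rows close. True AGB is
affine in clip01(vigor + η_h + η_c) with stage-specific ranges (SP
20–330, FP 50–700, TP 40–740 g/m², spanning the 0–700 g/m² a
multi-stage potato trial produces) plus Gaussian noise whose default sd
is 4 % of the stage span — leaving roughly 95 % of the within-stage AGB
variance explainable, a realistic ceiling for a well-executed trial.
The two auxiliary latents are deliberately invisible to the plot-mean
spectrum: η_h (sd 0.06) jitters canopy height multiplicatively, so only
the geometric dimension carries it; η_c (sd 0.04) sets the amplitude of
a lit/shaded soil banding along the furrows (period 6 px, zero mean),
so only the co-occurrence textures carry it. This gives every feature
dimension some unique signal, which is what makes richer dimension
combinations genuinely better on this generator.

**Soil-composition confound.** The lit/shaded soil split varies across
plots (uniform ± 0.18 by default, `soil_mix_range`), independent of
AGB. Plot-level indices absorb this soil signal; abundance-weighted
indices suppress it. Together with the cover-saturation mismatch (AGB
superlinear in cover, plot indices near-linear), this is the mechanism
that makes the soil-free VI[v] more correlated with AGB than VI[plot].
One caveat is intrinsic: synthetic VARI crosses zero between
soil-dominated and canopy-dominated plots, and multiplying a
sign-changing index by abundance scrambles its ordering — so the
VI[v]-improvement property is asserted for the five infrared-based
indices only.

**Heights and terrain.** Per-pixel canopy height is
h_max·v^0.7·(1 + η_h) inside the vegetation mask (summed non-soil
abundance > 0.5) and 0 elsewhere, with stage-specific h_max (0.25,
0.60, 0.50 m); the DEM is a smooth analytic surface and DSM = DEM +
height, so height recovery from DSM − DEM is exact by construction.
True plot FVC is the ROI mean of the summed non-soil abundance — under
linear mixing that sum *is* the subpixel vegetated-area fraction.

**Reflectance.** Each pixel is the exact convex combination of the
library spectra plus Gaussian noise (default sd 0.005, a typical
radiometric noise floor after calibration) and clipping to [0, 1].

**What the generator does not emulate** — and hence what passing tests
do not show about real data: no radiative transfer or BRDF, no
within-canopy spectral variability beyond the endmember set, no
georeferencing beyond a dummy affine, no photogrammetric DSM error, no
weeds or lodging, and field AGB heteroscedasticity richer than additive
Gaussian noise. Results on the generator validate the *machinery*, not
field accuracy.

## 9. Numerical choices and degenerate inputs

* All randomness flows from one integer seed through a documented
  splitting scheme (`derive_seed`: seed × purpose-tag hash), so every
  artifact is bit-reproducible and stages are decoupled.
* FCLS active-set tolerance 1e-10; constraints hold to ≤ 1e-8 for every
  output; abundance recovery on noise-free scenes is exact to ≤ 1e-6.
* Quantization maps a constant window to bin 0; zero-variance features
  contribute r = 0 in screens and weight 0 in RReliefF.
* Degenerate DPM scenes (NDVI_PP ≤ NDVI_NS) raise an error rather than
  returning unstable values; VI denominators of zero propagate as `NA`.
* Rasters are stored as multi-page 32-bit-float TIFF with an ESRI world
  file for the affine transform and a JSON sidecar for band metadata;
  elevation rasters are packed to [0, 1] with offset/scale recorded in
  the sidecar. Feature tables round-trip CSV at full double precision
  via 17-significant-digit formatting.

## 10. Problem sizes used by the tests

The shipped suites run the full 48-plot, three-stage trial (144
samples) for the pipeline-level properties, 20 independent seeds for
the selection-recovery and trend properties, and reduced 8-plot scenes
for per-module unit tests; oracle comparisons use 100–1000 random
instances per operation. These sizes give stable statistics for the
qualitative claims while keeping a complete run on a single CPU within
minutes.

## 11. Known limitations

* The texture screening requires AGB, so `extract_features` on
  unlabeled imagery needs an explicit `texture_source`.
* The Gini-importance route discretizes the target; rankings depend
  mildly on the class count (default 4).
* GLCM symmetrization and the gray-level count are conventions, both
  configurable; published studies rarely state them.
* The generator's ridge phase is shared across plots; estimator biases
  that depend on sub-pixel ridge alignment are therefore coherent
  rather than averaged out, which is the conservative direction for the
  FVC agreement checks.
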