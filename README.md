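# uavagb

Plot-level estimation of potato aboveground biomass (AGB, g/m²) from
six-band UAV multispectral reflectance imagery, with multi-dimensional
feature extraction, feature-parameter selection and regression
evaluation — plus a seeded synthetic-trial generator that makes every
stage of the pipeline verifiable against known ground truth.

## Who this is for

Crop-phenotyping and agricultural remote-sensing researchers who want a
tested, reproducible implementation of the common UAV biomass workflow:
extract many candidate predictors from imagery, rank them, and compare
regression models — without depending on a particular field campaign.

## What it computes

From a reflectance cube with bands at 450, 555, 660, 720, 750 and
840 nm, a DSM/DEM pair and a plot layout, the package extracts **39
candidate predictors per plot** in four dimensions:

- **SV — spectral (6).** Plot-level vegetation indices (NDVI, NDRE,
  MTCI, EVI2, VARI, OSAVI) corrected for soil background. Each pixel is
  decomposed by fully constrained least-squares (FCLS) unmixing

  R_mp = Σᵢ Abdᵢ·Rᵢ + ε,  0 ≤ Abdᵢ ≤ 1,  Σᵢ Abdᵢ = 1,

  against a stage-specific endmember library (lit/shaded leaf,
  lit/shaded soil, flower, yellow leaf). The soil-free index is
  VI[v] = VI[plot] × (summed non-soil abundance).
- **TV — texture (6).** Gray-level co-occurrence matrix (GLCM)
  statistics — VAR, HOM, CON, DIS, ENT, SEC — computed per band in
  three ridge-relative directions (parallel, perpendicular, 45°); the
  band/direction pair most correlated with AGB is kept.
- **GV — geometric (2).** Canopy height as mean positive DSM − DEM,
  and fractional vegetation cover (FVC) by the dimidiate pixel model
  FVC = (NDVI − NDVI_NS)/(NDVI_PP − NDVI_NS) with scene-percentile
  bounds, cross-checkable against an SVM pixel classifier.
- **FDV — frequency-domain (25).** Harmonic decomposition of the
  six-point band spectrum: A₀/2, and for orders t = 1…6 the
  coefficients Aₜ, Bₜ, amplitude Cₜ = √(Aₜ²+Bₜ²) and phase
  φₜ = atan2(Aₜ, Bₜ).

Candidate predictors are ranked by **RReliefF**, **random-forest Gini
importance** (quantile-discretized target) and **random-forest
out-of-bag permutation importance** (IMP_F = Σ(E₂−E₁)/K), the top ten
retained, and **PLSR** and **random-forest regression** fitted on a
stage-stratified calibration/validation split. Models are scored by
R², RMSE, MAE and nRMSE over the four-selection grid and over the
seven combinations of dimensions that include SV.

The synthetic generator emulates a 48-plot factorial potato trial
(4 varieties × 4 NPK fertilization gradients × 3 repetitions) at three
growth stages, with ridge-periodic canopies, linear spectral mixing and
an AGB model tied to latent canopy vigor — see the methods vignette
(`vignettes/uavagb-methods.Rmd`) for the full generative model.

## Worked example

```r
library(uavagb)

scenes <- lapply(c("SP", "FP", "TP"), function(st)
  generate_scene(scene_config(seed = 42, stage = st)))
ft <- extract_features(scenes)           # 144 samples x 39 features
ranking <- rf_oob_importance(ft, seed = 42)
head(ranking[order(ranking$rank), c("feature", "weight", "rank")], 5)
#>   feature    weight rank
#>  HEIGHT_m 17244.017    1
#>        B6  7163.657    2
#>      PHI2  5084.313    3
#>      PHI4  4651.162    4
#>        A2  2807.559    5

report <- run_experiment(ft, selections = "rf_oob",
                         regressions = c("plsr", "rfr"), seed = 42)
report[report$partition == "validation",
       c("selection", "regression", "R2", "RMSE_g_m2", "MAE_g_m2",
         "nRMSE_pct")]
#>  selection regression    R2 RMSE_g_m2 MAE_g_m2 nRMSE_pct
#>     rf_oob       plsr 0.945      46.2     35.9      18.8
#>     rf_oob        rfr 0.941      48.0     36.3      19.5
```

Canopy height dominates the out-of-bag ranking (it carries growth
information the spectra alone miss), harmonic terms follow, and both
regressions explain ≈94 % of the validation AGB variance on this
synthetic trial; RMSE is in g/m² and nRMSE is the RMSE as a percentage
of mean observed AGB.

The same workflow runs from the shell via the thin wrapper in
`inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "uavagb", package = "uavagb"))')" \
  all --out-dir run1 --seed 42
```

which writes scenes (multi-page float TIFF + world files), the feature
table, three importance rankings, and selection/combination reports as
CSV and JSON under `run1/`.

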