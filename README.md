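# hmrconv

Collimator-aware standardization of the ¹²³I-MIBG heart-to-mediastinum
ratio (HMR).

The HMR of planar ¹²³I-MIBG scintigraphy — mean counts in a cardiac ROI
over mean counts in a mediastinal ROI — is a widely used cardiac
sympathetic-innervation index, but it is not comparable across gamma
cameras: the high-energy lines of ¹²³I (440–539 keV, ~2.5 % of decays)
penetrate the septa of low-energy collimators and dilute image contrast.
Systems are harmonized through a **conversion coefficient** measured on
a dedicated calibration phantom,

```
cc = ((HMR_ant + HMR_post)/2 − 1) / ((2.6 + 3.5)/2 − 1)
```

where 2.6 / 3.5 are the phantom's designated anterior / posterior HMRs.
`hmrconv` is a desk-scale, fully seeded reimplementation of that
standardization pipeline for physicists and methodologists who want to
study it without phantom experiments or Monte Carlo transport runs:

* a **digital three-layer calibration phantom** whose heart activity is
  solved exactly so an ideal projection reproduces the designated HMRs
  (`build_phantom()`, `calibrate_phantom()`);
* an **analytic multi-energy projector** with Beer–Lambert attenuation,
  collimator/detector blur, energy window, septal-penetration
  contamination and Poisson noise (`simulate_planar()`,
  `simulate_conversion()`);
* the **analysis chain**: standardized ROIs, HMRs, conversion
  coefficients, the compensation line Y = 1.27 X − 0.15 onto the
  experimental scale, and the 1 % penetration exclusion filter
  (`compute_hmr()`, `conversion_coefficient()`, `compensate()`,
  `penetration_filter()`);
* a **gradient-boosted regression** predicting coefficients from hole
  diameter, septal thickness and collimator length, with 3:2 split,
  fourfold-CV grid search, RMSE, permutation importances and a linear
  baseline (`run_grid()`, `train_gbm()`, `train_linear()`,
  `permutation_importance()`);
* bundled **presets** for 18 commercial collimators and 8 camera
  detector configurations (`collimator_presets()`, `detector_presets()`,
  `discovery_presets()`).

## Worked example

Simulate the Discovery MEGP collimator (hole 3.0 mm, septum 1.05 mm,
length 58 mm) on the calibrated phantom under the standard detector:

```r
library(hmrconv)
phantom <- calibrate_phantom(build_phantom())
ideal_hmr(phantom)
#>  anterior posterior
#>       2.6       3.5

det <- detector_spec()                      # 9.5 mm NaI, 3.8 mm, 9.8 %
acq <- acquisition_spec(total_photons = 1e7, seed = 42)
rec <- simulate_conversion(phantom, discovery_presets()$MEGP, det, acq,
                           n_replicates = 5, seed = 42)
rec[, c("label", "hmr_ant", "hmr_post", "raw_cc",
        "compensated_cc", "cc_sd")]
#>   label hmr_ant hmr_post raw_cc compensated_cc    cc_sd
#> 1  MEGP   2.353    2.985  0.814         0.8838 0.007292
```

Reading this: septal penetration and scatter pull the measured HMRs
(2.35 / 2.99) below the designated 2.6 / 3.5, giving a raw coefficient
of 0.814; the compensation line maps it to 0.884 on the experimental
scale, with a replicate SD of 0.007. A medium-energy collimator passes
only ~11 % of the 529 keV line through its septa, against ~57 % for
LEHR — which is why the LEHR coefficient ends up near 0.55 instead:

```r
sapply(discovery_presets(), septal_penetration, energy_kev = 529)
#>      LEHR     ELEGP      MEGP
#> 0.5741918 0.4716755 0.1118231
```

To train the predictor, regenerate the coefficient table over the
8 × 12 × 9 design grid and follow the reference protocol:

```r
records <- run_grid(phantom, det, acquisition_spec(total_photons = 1e6),
                    seed = 101)                    # ~4 min, 769 designs
split <- split_dataset(records, seed = 101)
gbm <- train_gbm(split$train, folds = 4, seed = 101)
rmse(gbm, split$validation)                        # ~0.02
rmse(train_linear(split$train), split$validation)  # ~0.056
predict_coefficient(gbm, discovery_presets()$MEGP) # ~0.89
```

A thin command-line wrapper over these functions is provided in
`inst/scripts/hmrconv-cli.R`.

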