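# lsdox — learned spectral decoloring for photoacoustic oximetry

Multispectral photoacoustic imaging encodes blood oxygen saturation
(sO₂ = HbO₂ / (Hb + HbO₂)) in the wavelength dependence of the per-pixel
initial pressure, p₀(λ) ∝ Γ·μₐ(λ)·φ(λ). The standard estimator, linear
unmixing (LU), fits the Hb and HbO₂ absorption spectra to the signal and
assumes p₀(λ) ∝ μₐ(λ) — but the fluence φ(λ) itself changes with
wavelength and depth, *spectrally coloring* the measured spectrum and
biasing LU increasingly with depth.

`lsdox` implements **learned spectral decoloring (LSD)**: a fully
connected network

    f_LSD : S_p0 ∈ ℝⁿ → sO₂,   with Σᵢ S_p0,λᵢ = 1,

trained purely on simulated, fluence-colored pixel spectra, so that many
differently colored spectra map to the same sO₂. Sum normalization
discards amplitude, removing the need to calibrate simulation to device.
The package is aimed at researchers in quantitative photoacoustics who
want a reproducible in-silico pipeline: seeded tissue-phantom generators,
an optical forward model, spectra extraction with the CNR ≥ 2 region rule,
the LSD regressor, the LU baseline, and error/time-series evaluation
utilities (including the Severinghaus pO₂→sO₂ conversion).

## What is inside

| Area | Functions |
|---|---|
| Chromophores | `load_chromophore_table()`, `blood_absorption()`, `tissue_absorption()`, `tissue_scattering()` |
| Phantoms | `phantom_spec()`, `sample_generic()`, `sample_flow()`, `sample_forearm()`, `optical_volume()` |
| Forward model | `fluence_layered()`, `fluence_mc()` (Rcpp voxel Monte Carlo), `initial_pressure()`, `simulate_multispectral()` |
| Spectra | `normalize_spectrum()`, `cnr_mask()`, `amplitude_mask()`, `filter_min_size()`, `average_frames()`, `build_dataset()` |
| LSD model | `lsd_config()`, `build_model()`, `train_lsd()`, `predict()`, `predict_image()` |
| LU baseline | `linear_unmix()`, `unmix_image()` |
| Evaluation | `relative_error()`, `error_summary()`, `severinghaus_so2()`, `roi_time_series()`, `dynamic_range()` |
| Pipeline | `resolve_wavelengths()`, `simulate_dataset()`, `run_insilico_experiment()`, `run_pipeline()` |

Three synthetic domains mirror the study designs: *generic tissue*
(vessels in a weakly absorbing background, one shared sO₂ ~ U(0,1),
26 wavelengths 700–950 nm), *flow phantom* (one blood tube in agar,
17 wavelengths, pencil beam), and *forearm* (skin layers, bone, artery,
vein, vessels with the published tissue property ranges). The methods
vignette (`vignettes/learned-spectral-decoloring.Rmd`) documents every
model, parameter and design decision.

## Worked example

A complete desk-scale experiment — simulate 96 generic-tissue phantoms,
extract ~7 × 10⁴ labeled pixel spectra, train the LSD network
(26→52×4→1, leaky ReLU, 20% dropout), evaluate on the held-out 20%
split, and compare with linear unmixing on the same rows:

```r
library(lsdox)
exp <- run_insilico_experiment("generic", seed = 1, compare_lu = TRUE)
exp
#> <lsd_experiment> generic set: 14390 test spectra from 96 phantoms
#> LSD <error_summary> n = 14390
#>   relative: median 4.9%, IQR (2.0%, 11.3%)
#>   absolute: median 2.1 pp, IQR (0.8, 5.5) pp
#> LU <error_summary> n = 14390
#>   relative: median 33.6%, IQR (12.5%, 96.2%)
#>   absolute: median 16.7 pp, IQR (6.5, 32.7) pp
```

Reading this: half of the held-out vessel pixels are estimated within
~5% relative error (about 2 percentage points of sO₂), while linear
unmixing on exactly the same colored spectra is off by a median of ~17
percentage points — the depth-dependent fluence bias that LSD learns to
undo. (Exact numbers vary by a percent or two with the seed; the
absolute-error median stays well below 10 pp on all three domains.)

Pixel-wise maps for a multispectral image stack:

```r
exp_flow <- run_insilico_experiment("flow", seed = 1)   # 17-wavelength model
vol   <- sample_flow(phantom_spec("flow", seed = 7))
stack <- simulate_multispectral(vol, resolve_wavelengths("flow"))
so2_lsd <- predict_image(exp_flow$model, stack, mask = vol$labels == 2)
so2_lu  <- unmix_image(stack, mask = vol$labels == 2)$so2
```

A thin command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/lsd.R run --config inst/presets/generic.yaml --out out/
Rscript inst/cli/lsd.R predict --model out/model.rds \
        --dataset out/dataset.csv --out predictions.csv
```

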