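# swallowEMG

Automatic monitoring of fluid intake is an open problem in geriatric care:
dehydration is common in adults over 65, and manual fluid charting is
unreliable. One candidate sensing route is surface electromyography (sEMG)
of the sternohyoid muscles — every swallow produces a burst in the neck sEMG
whose energy scales with the swallowed bolus. **swallowEMG** implements the
complete analysis chain for two-channel sternohyoid recordings, for signal-
processing and biomedical-ML researchers who want a tested, reproducible
reference implementation:

- **Preprocessing** — Kaiser-window FIR band-pass (20–400 Hz, 60 dB
  stopband), zero-phase application, 1000 ms moving-RMS envelope, burst
  localization at the envelope argmax, extraction of the 1500 ms burst
  window and the last-1.5 s baseline-noise window.
- **Feature library** — 46 time- and frequency-domain features per window
  (IEMG, MAV family, RMS, waveform length, Willison amplitude, zero
  crossings, slope-sign changes, temporal and spectral moments, median/mean/
  peak frequency, Welch mean power density, Higuchi fractal dimension with
  k·max = 128, sample/approximate entropy with m = 2, r = 0.2 σ, …).
- **Classification** — per-subject liquid vs non-liquid swallowing events
  (16 liquid sips against 5 saliva bursts + 11 noise windows) with LDA and
  1-nearest-neighbour under leave-one-out cross-validation; accuracy,
  sensitivity, specificity, precision and F-score
  (F = 2·P·S / (P + S)) as cohort mean ± SD.
- **Volume estimation** — per-sip volume in mL by (i) the mean-sip baseline,
  (ii) 5-fold cross-validated ordinary least squares, and (iii) a
  15-unit tanh network trained by Levenberg–Marquardt with validation-based
  early stopping; scored by RMSE and the mean estimation error
  EE (%) = mean(|v̂ᵢ − vᵢ| / vᵢ) × 100.
- **Stepwise forward selection** around either task, with plateau stopping
  and a one-way ANOVA across feature-set sizes.
- **Synthetic cohort generator** emulating the drinking protocol
  (5 saliva + 5 cup + 5 bottle + 5 straw sips + 1 maximum-capacity swallow
  per subject, 10 s two-channel recordings at 1 kHz), with seeded,
  bit-reproducible output — so the whole pipeline runs and is tested
  without any subject data.

## Worked example

```r
library(swallowEMG)

# simulate one subject's 21-recording protocol and extract features
cohort <- generate_cohort(synth_config(), n_subjects = 1, seed = 42)
features <- extract_cohort_features(cohort)

# classify liquid vs non-liquid events (LOOCV, 1-nearest neighbour)
ds <- assemble_subject_dataset(features, "S01")
round(loocv_evaluate(ds, c("IEMG", "VCF"), model = "KNN1")$metrics, 2)
#>    accuracy sensitivity specificity   precision     f_score
#>       90.62      100.00       81.25       84.21       91.43

# estimate sip volumes from the burst IEMG by cross-validated OLS
liquid <- features[features$kind == "burst" & features$volume_mL > 0, ]
set.seed(1)
fit <- linear_regression_cv(liquid, liquid$volume_mL, "IEMG")
round(c(rmse_mL = fit$rmse_mL, ee_pct = fit$ee_pct), 2)
#> rmse_mL  ee_pct
#>    0.37    3.02

# the naive alternative: predict every sip by the subject's mean
round(mean_sip_baseline(list(S01 = liquid$volume_mL))$error_pct[1], 2)
#> [1] 56.94
```

With two features this subject's 32 LOOCV folds classify at 90.6% accuracy
(all 16 liquid sips found, 3 of 16 non-liquid events confused), and a
single energy feature predicts the subject's sip volumes to 0.37 mL RMSE /
3.0% mean error — against 56.9% for the constant mean-sip predictor. The
synthetic signal model is deliberately clean; these numbers characterise
the pipeline, not real-world performance (see the methods vignette).

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
pipeline; each is a thin script over the package functions and writes its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # 11-subject cohort -> results/cohort/
Rscript analysis/02_features.R    # -> results/feature_matrix.csv
Rscript analysis/03_classify.R    # LDA + 1-NN selection traces and metrics
Rscript analysis/04_estimate.R    # mean-sip / OLS / ANN volume estimation
```

## Documentation

The methods vignette (`vignettes/swallow-emg-methods.Rmd`) describes the
signal model and its assumptions, every tunable parameter with units and
defaults, the numerical choices (filter design, shrinkage, tie-breaks,
degenerate inputs), what the synthetic generator does and does not emulate,
and the package's known limitations.
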