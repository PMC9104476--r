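---
title: "Methods: swallow detection and fluid-intake estimation from neck sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swallow detection and fluid-intake estimation from neck sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swallowEMG)
```

## The problem

Dehydration in older adults is common, and clinical fluid-intake charting is
manual and unreliable. A wearable route to automatic intake monitoring is
surface electromyography (sEMG) over the infrahyoid neck muscles: every
swallow recruits the sternohyoid muscles and produces a transient burst in
the sEMG whose energy grows with the swallowed bolus. This package
implements the full analysis chain for that idea on two-channel
(left/right sternohyoid) recordings:

1. **Preprocessing** — band-pass filtering, envelope-based burst
   localization, fixed-width window extraction;
2. **Feature extraction** — a 46-feature time- and frequency-domain library
   per window;
3. **Classification** — per-subject discrimination of liquid swallows from
   non-liquid events (saliva swallows and baseline noise) with LDA and
   1-nearest-neighbour under leave-one-out cross-validation (LOOCV);
4. **Volume estimation** — per-sip volume regression by a mean-sip
   baseline, cross-validated ordinary least squares, and a shallow
   Levenberg–Marquardt-trained network;
5. **Stepwise forward feature selection** wrapped around either task.

Because no subject data ship with the package, a seeded synthetic generator
(`synth_config()`, `generate_cohort()`) emulates the acquisition protocol so
that every stage is exercised end-to-end by code alone.

## The drinking protocol and its synthetic emulation

The emulated protocol records 21 ten-second trials per subject at 1 kHz:
five saliva swallows, five sips each from a cup, a bottle and a straw
(self-selected sip sizes, weighed per sip), and one maximum-capacity swallow
of the subject's largest cup volume plus 5 mL. That yields 16 liquid-swallow
observations per subject; the non-liquid class pairs the 5 saliva bursts
with 11 baseline-noise windows, giving a balanced 16/16 problem.

The generator models each channel as Gaussian baseline noise plus one burst
of band-limited (20–400 Hz) Gaussian noise under a Hann envelope. The
couplings the analysis assumes are explicit parameters:

| parameter | default | meaning |
|---|---|---|
| `noise_sigma_uV` | 6 | SD of baseline noise (µV) |
| `burst_base_uV` | 15 | peak envelope amplitude at zero volume (µV) |
| `burst_gain_uV_per_mL` | 2.5 | amplitude increase per mL |
| `burst_dur_ms` | (1400, 5) | burst duration = base + slope·volume, capped at 1500 ms |
| `container_volume_dists` | straw 8±3, cup 15±5, bottle 18±6 mL | per-container sip-volume distributions, truncated at 1 mL |
| `saliva_effective_mL` | 1.5 | effective volume driving the (small) saliva burst |
| `lr_asymmetry` | 0.85 | right/left channel gain ratio |

Design notes:

* **Burst model.** A Hann-enveloped band-noise burst is the simplest model
  with a tunable signal-to-noise ratio and a monotone volume–energy
  coupling; no claim of physiological waveform realism is made. The carrier
  is synthesized in the frequency domain (bins outside 20–400 Hz zeroed), so
  its band limitation is exact rather than approximate.
* **Durations.** Swallow bursts occupy roughly 1–1.5 s, and the analysis
  window is sized at 1500 ms precisely to hold one burst; the default puts a
  typical sip near 1.5 s. Sub-second bursts would leave the 1000 ms RMS
  envelope with a flat top whose argmax wanders by 100–200 ms under noise —
  the localization tests document this regime boundary.
* **Container means** were chosen to bracket published per-subject mean sip
  volumes (about 7–24 mL) with straw sips smallest, which is the documented
  behavioural pattern.
* **Ground truth.** The true burst centre is stored in each synthetic
  recording for testing localization only; the pipeline never reads it.

What the generator deliberately does **not** emulate: motion and swallowing
artefacts, electrode placement variability, non-stationary baselines,
between-subject differences in burst morphology, and the container-specific
burst shapes real data would show. Passing tests therefore demonstrate that
the algorithms are implemented correctly and behave as designed under the
stated couplings — not that the method achieves any particular performance
on real recordings. Synthetic classification accuracies (typically > 98%)
are higher than what real sternohyoid data yield, because the synthetic
liquid/non-liquid contrast is governed by a single clean amplitude coupling.

## Preprocessing

**Filter.** A Kaiser-window FIR band-pass, 20–400 Hz, stopband attenuation
60 dB. The "steepness" convention maps 0.85 to a transition width of
`(1 − 0.85) × 20 Hz = 3 Hz` about each edge; the Kaiser β and order follow
the standard attenuation formulas (β = 0.1102(A − 8.7), order
≈ (A − 8)/(2.285 Δω), about 1200 taps at 1 kHz). What is contractually
verified is the magnitude response — at least 60 dB down at 10 and 450 Hz,
under 1 dB of ripple across 40–380 Hz — not coefficient identity with any
toolbox. The symmetric kernel is applied with group-delay compensation, so
filtering is zero-phase and burst timing is preserved (a symmetric pulse's
centre of mass moves by less than one sample).

**Envelope and localization.** A centred 1000 ms moving-RMS envelope is
computed per channel with truncated windows at the edges (zero-padding would
manufacture artificial edge peaks that could hijack the argmax). The burst
centre is the global envelope maximum of the channel-mean envelope, earliest
index on ties, clamped so a 1500-sample window fits.

**Windows.** The burst window spans 750 samples either side of the centre;
the baseline window is the recording's last 1500 samples. If a late burst
makes the two overlap, the windows are still returned with a warning — the
original workflow relied on visual inspection for baseline purity, which an
automated pipeline can only flag, not reproduce.

## The feature library

All 46 features are computed per 1500-sample window, per channel, and the
two channels are combined by averaging (the default) or concatenation —
whether the original analysis averaged or concatenated is unstated, so both
are provided. Amplitude features (IEMG, MAV and its weighted variants, SSI,
VAR, RMS, V-orders, LOG, temporal moments, square-root summaries, kurtosis,
skewness, AFB, AUC), rate features (WL, AAC, DASDV, MFL), threshold counts
(MYOP, WAMP, ZC, SSC), complexity measures (Higuchi fractal dimension with
k<sub>max</sub> = 128; sample and approximate entropy with m = 2,
r = 0.2 SD), and spectral features from a mean-removed one-sided periodogram
(moments SM1–SM3, MNF, MDF, PKF, FR, PSDd, VCF, dPDR, PSR) plus a Welch
mean power density (MPD; 256-sample Hann segments, 50% overlap).

Choices worth flagging, all configurable:

* **MYOP threshold** "5.5 µ" is read as 5.5 µV on the filtered signal —
  recordings are in microvolts and the unit character is truncated in the
  source table.
* **WAMP/ZC thresholds** are 0.3 × the SD of the same recording's baseline
  window, so activity counts are referenced to each recording's own noise
  floor (`threshold_ctx()`).
* **SSC** is computed without a threshold (the library lists none), as a
  count of interior slope-sign reversals.
* **MMAV** duplicates the MAV1 formula under its own name: the catalogue
  the library derives from defines MMAV1/MMAV2 only, yet the library lists
  MAV1, MAV2 *and* MMAV. Selection tolerates the collinearity naturally.
* **ASM** uses exponent 0.75 on the central 60% of samples and 0.5 on the
  tails, following the enhanced-feature literature the abbreviation comes
  from. This is flagged prominently because ASM is a headline regression
  feature.
* **AFB** is the window's maximum absolute amplitude — windows contain one
  burst by construction, so the burst-detection variant is unnecessary.
* **Kurtosis** is the non-excess Pearson ratio.
* **MDF** takes the first frequency bin whose cumulative power reaches half
  the total, without interpolation.
* **LOG** guards zeros with ε = 1e−12 inside the logarithm; a constant
  window is a hard error (MFL, skewness/kurtosis and the entropies are all
  undefined there).
* **MPD vs MNP.** MPD deliberately uses the Welch estimator so that mean
  power (periodogram) and mean power density remain distinct features.

Entropies and the Higuchi curve-length scan are O(N²)/O(N k<sub>max</sub>)
pair scans implemented in compiled code; the test suite pins them to naive
R double-loop oracles at N = 200 to 1e−10.

## Classification

Per subject, each of the 32 observations is held out once; the model is fit
on the remaining 31. Features are z-scored *inside* each fold using training
statistics only — the source analysis is silent on scaling, but 1-NN on raw
mixed-unit features would be dominated by whichever feature has the largest
scale, so per-fold standardization is the default (and refitting it per fold
avoids information leak; a label-permutation control in the tests confirms
chance-level accuracy). LDA uses the pooled covariance with a shrinkage
ladder toward its diagonal (and ultimately a ridge) because 31 training
points with several features can be near-singular. 1-NN breaks distance
ties by the lowest training index so results are reproducible. Confusion
counts are pooled over the 32 folds and scored as accuracy, sensitivity,
specificity, precision and F-score (liquid = positive class), reported
per subject and as cohort mean ± SD.

The 11 baseline windows of the non-liquid class are the baselines of the
first 11 recordings in task order — the original choice of 11 is unstated,
so the rule here is deterministic but arbitrary.

## Volume estimation

Only liquid sips (volume > 0) enter estimation; saliva and noise windows
carry no volume. Errors are RMSE in mL and the mean relative estimation
error EE = mean(|predicted − actual| / actual) × 100.

* **Mean-sip baseline** predicts every sip by the subject's mean sip volume;
  its across-all row aggregates per-subject columns as mean of means, SD of
  means, and mean of errors. Feeding a published 11-subject summary table
  through this aggregation reproduces that table's own across-all row, which
  the acceptance checks exploit.
* **Linear regression**: intercept plus one linear term per selected
  feature, ordinary least squares, 5-fold cross-validation with a seeded
  shuffle; RMSE/EE pooled over held-out predictions. Rank-deficient designs
  (e.g. MMAV with MAV1) fall back to the minimum-norm solution with a
  warning.
* **Shallow network**: 15 tanh units, linear output, trained by
  Levenberg–Marquardt (damping ×10 up / ÷10 down, gradient tolerance 1e−7,
  at most 200 iterations) on a random 70/15/15 train/validation/test split
  with early stopping after 6 consecutive validation failures; best of
  `restarts` random initializations by validation error. Inputs and target
  are z-scored on the training split. Errors are scored on held-out test
  sips by default (configurable to all sips); with 16 sips per subject the
  test split holds 2–3 sips, so per-subject ANN errors are noisy — the
  cohort mean ± SD is the stable summary.

Whether published per-subject RMSEs were pooled or averaged is ambiguous,
so `estimate_cohort()` reports both the per-subject mean ± SD and the
pooled value.

## Stepwise forward selection

`forward_select()` wraps any evaluator: at each step every remaining
candidate joins the current set, the best cohort-mean metric wins (ties by
the canonical `feature_names()` order), and the search stops at a plateau
(improvement ≤ ε, default 0), at `max_features` (default 10 in the
function; the analysis scripts use 5 for classification), or on exhaustion.
The driving metric is accuracy for classification and RMSE (minimized) for
estimation. Two caveats are documented rather than hidden:

* Greedy forward selection is not optimal for non-additive metrics: the
  test suite demonstrates that under LOOCV accuracy the greedy subset can
  differ from the exhaustive best subset, and verifies exact equivalence
  where it must hold (additive separation scores).
* Selection is performed on the same LOOCV estimates that are reported,
  mirroring the original procedure; the reported metric at the selected
  size is therefore optimistically biased (selection bias), which matters
  when comparing against external baselines.

A one-way ANOVA across feature-set sizes (`anova_across_steps()`) asks
whether the per-subject metric changes as features are added, with
descriptive pairwise comparisons.

## Problem sizes and numerical choices

The analysis scripts and acceptance checks run an 11-subject cohort
(231 recordings, 462 windows, 176 liquid sips), 200 recordings for
localization, 50 random windows/datasets for the oracle equivalences, and
10 seeded cohorts for the estimator-vs-baseline comparison — sizes chosen to
exercise every code path at full fidelity while a complete run stays in the
single-digit minutes. All randomness flows from explicit seeds; identical
seeds give bit-identical cohorts, selections and reports.

Degenerate inputs are errors, not silent NaNs: constant windows (undefined
MFL/entropies/moment ratios), zero noise SD, zero total spectral power,
empty feature subsets, non-positive volumes in EE, and any non-finite
feature value all raise immediately.

## Known limitations

* Synthetic-only validation; none of the numeric results transfer to real
  recordings, and the published cohort's headline numbers depend on
  unreleased subject data.
* Between-subject heterogeneity is limited to noise realizations and sip
  draws — real cohorts differ in baseline level, burst morphology and
  volume habits, so across-subject spreads here are narrower than published
  ones.
* Saliva bursts — small, with no documented amplitude to calibrate against —
  localize slightly worse than liquid bursts; the localization guarantee is
  stated for liquid-swallow recordings.
* One burst per recording is assumed; multi-swallow trials and artefact
  rejection are out of scope.
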