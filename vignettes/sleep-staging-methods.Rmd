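---
title: "Multimodal sleep staging: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal sleep staging: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Polysomnography scores sleep in 30-second epochs into wake, N1, N2, N3 and
REM, but requires a laboratory. Unobtrusive alternatives rely on secondary
physiology: body movement (wrist actigraphy, ACT), cardiac rhythm (heart
rate variability, HRV, from RR intervals), and breathing (respiratory rate
variability, RRV, from a belt — or estimated from a single-lead ECG as
ECG-derived respiration, EDR). `sleepstager` implements that pipeline end
to end: stream alignment on an epoch grid, signal cleaning, windowed
feature extraction, leakage-safe model training at three stage
granularities (5-class AASM, wake/NREM/REM, sleep--wake) and four modality
combinations (ACT, ACT+HRV, ACT+HRV+RRV, ACT+HRV+ED-RRV), and
MCC-centred evaluation. Because clinical overnight datasets are
access-restricted, the package ships a synthetic cohort generator rich
enough to exercise every stage, including EDR.

## Data model and alignment

All streams live on a shared grid of 30-second epochs covering half-open
intervals `[t, t + 30)`. Alignment restricts the grid to the intersection
of the stream spans and the in-bed interval; epochs partially outside are
dropped from features and labels alike (the conservative choice — a
truncated epoch has ill-defined counts). Each NN interval is assigned to
the epoch containing its *ending* beat, since an inter-beat interval is
realized at its terminating beat. Recordings with total sleep time below
120 minutes (0.5 min per non-wake epoch) fail QC, and train/test splitting
is always at the participant level, with the train side rounded half-up
(1120 participants at 0.8 give 896/224).

## Signal cleaning

RR series are cleaned in three steps: bounds (`[300, 2000]` ms), the 20%
relative-change ectopy rule against the previous kept interval, and linear
interpolation of removed positions (flagged, length-preserving). The
thresholds are the conventional defaults of HRV practice, made explicit
and configurable, since only the step names are canonical.

Respiration is band-passed with a second-order Butterworth (0.1--0.35 Hz,
the adult breathing band), applied forward--backward so breath timings are
not phase-shifted; residual drift is removed by subtracting a 0.05 Hz
low-pass trend; the signal is resampled to 32 Hz with anti-alias filtering
and min--max normalized to `[0, 1]` (a constant signal is degenerate and
rejected).

## ECG-derived respiration

Beat annotations come from an adaptive-threshold R-peak detector
(refractory 250 ms) or are supplied externally. The trough preceding each
R-peak is the minimum in the 100 ms window before it; both windows are
physiological QRS bounds. The per-beat measure is the arithmetic mean of
R-peak and trough amplitudes — the phrase "mean amplitude between peak and
trough" is ambiguous in the EDR literature, so the R-minus-trough
difference is available via `method = "difference"`. The beat-sampled
series is cubic-interpolated onto a 4 Hz grid (comfortably above twice the
0.35 Hz band top; a beat-sampled series cannot be filtered directly) and
then cleaned exactly like the belt signal. On synthetic amplitude-modulated
ECG the pipeline recovers modulation frequencies of 0.15--0.30 Hz within
±0.02 Hz, which is what licenses using ED-RRV features in place of belt
RRV.

## Feature extraction

* **ACT (370)**: 10 statistics (mean, median, SD, min, max, IQR, skewness,
  kurtosis, RMS, zero fraction) over 37 window configurations (centered
  lengths 3--19 epochs odd, trailing 1--20, leading 2--9 — 30 s to 10 min).
* **HRV (30)**: 12 time-domain, 8 frequency-domain and 10 nonlinear
  features per epoch, computed on a centered 5-minute (11-epoch) window.
  Thirty seconds of NN intervals cannot support VLF/LF estimation, hence
  the 5-minute window. Band powers (VLF 0.0033--0.04, LF 0.04--0.15, HF
  0.15--0.4 Hz) come from a periodogram of the 4 Hz-interpolated NN series.
* **RRV (60)**: 20 breath-to-breath metrics over centered 5-, 7- and
  9-minute windows (stride one epoch). `MCVBB = MadBB / MedianBB`
  normalizes absolute variability by the median breath interval and is the
  most stage-discriminative respiratory feature. Windows with fewer than 4
  detected breaths are zero-filled and flagged — the rule for spans where
  no respiration could be recovered.
* **Sequence-model inputs**: raw activity counts, eight basic HRV features
  and four simple RRV features, instead of the engineered manifests.

Degenerate statistics (entropy on too-short windows, ratios with zero
denominators, skewness of constant windows) emit 0 rather than NaN so
matrices remain model-ready; flags preserve the information. Breath
detection uses topographic prominence ≥ 0.1 (normalized units) and 2 s
minimum peak spacing (≤ 30 breaths/min). RRV frequency bands default to
the HRV band layout but are configurable, since the physiological meaning
of an RRV HF band is debatable.

## Training without leakage

Cross-validation folds are grouped by participant: epoch-level folds would
put one subject's adjacent epochs on both sides of a fold boundary and
inflate validation scores. Within each fold, z-score standardization and
select-k-best (univariate ANOVA F) are fitted on the training folds only;
the recompute oracle for those parameters is part of the test suite.
Candidate hyperparameters are scored by mean validation MCC and the best
set is refit on all training rows. Five classical families are provided
(SVM, MLP, AdaBoost as SAMME over shallow trees, random forest, gradient
boosting); search is exhaustive grid for the first three and trial-budgeted
random search for the ensembles (the "tpe" strategy name is accepted and
maps to the budgeted search). Default spaces are deliberately small desk
scale; the large published budgets are configuration values, not defaults.

The sequence model is a compact tanh recurrent network reading a centered
window (10/25/50 min, i.e. 20/100 epoch inputs of 2x minutes) up to its
center epoch, with a softmax head, trained with Adam on cross-entropy and
checkpointed at each new minimum of validation loss. Windows never cross
participant boundaries; edges are zero-padded and masked; inputs are
z-normalized with training-set statistics. Loss choice (cross-entropy) and
architecture are deliberately pluggable defaults.

## Evaluation

The primary metric is the Matthews correlation coefficient. For two
classes it is the classical confusion-matrix formula; for three and five
classes the generalized multiclass correlation, which reduces to the
binary formula on 2x2 input (verified to 1e-12 in the tests) and maps any
zero denominator to 0. Accuracy, F1, precision, recall and specificity are
macro-averaged one-vs-rest for multiclass tasks and refer to the positive
(SLEEP) class in the binary task. Metrics are aggregated per participant
(median and IQR across participants, matching the boxplot convention), and
conditions are compared with two-sided Mann--Whitney U tests under
Bonferroni correction at alpha = .05, with an explicit, caller-declared
family size because implicit families are a common source of
irreproducibility.

## The synthetic cohort

The generator's defaults define the study conditions used throughout the
tests:

* **Hypnogram**: first-order Markov chain over the five stages, starting
  awake, whose stationary distribution (~19% wake, 5% N1, 40% N2, 20% N3,
  17% REM) sits near typical overnight stage proportions. Explicit
  90-minute REM cyclicity is not modelled — a first-order chain suffices to
  test classifiers; cyclic structure would only matter for models that
  exploit long-range periodicity.
* **Activity**: zero-inflated negative binomial, stage means 150 (wake) /
  20 / 8 / 2 (N3) / 8 counts, zero-inflation 0.05--0.85.
* **Cardiac**: mean NN 800 (wake) to 1000 ms (N3), spread 50 down to
  15 ms, with respiratory sinus arrhythmia implemented as an RSA-gain
  (10--40 ms) coupling to the respiration phase; beats by
  integrate-and-fire.
* **Respiration**: per-breath period jitter 2--5% in NREM versus 15% in
  REM and 12% in wake, rates 0.21--0.27 Hz; ground-truth breath times are
  recorded.
* **ECG**: QRS-like template (trough 40 ms before the peak) at each beat,
  amplitude-modulated by respiration (depth 0.3) plus white noise
  (SD 0.02); 256 Hz. The belt waveform is emitted at 32 Hz directly — the
  pipeline's post-cleaning rate — keeping 8-hour cohorts light; the
  256→32 Hz decimation path is exercised separately in the preprocessing
  tests.

Per-participant seeds derive from the master seed by a fixed affine
counter scheme, so cohorts are byte-reproducible. Nights default to 960
epochs (8 h) and cohorts to 20 participants; end-to-end checks train on 16
and test on 4. What the simulator does *not* emulate: real ECG morphology
(P/T waves), apnea events, posture artifacts, scorer disagreement, and
between-stage transition dynamics beyond first order. Passing tests
therefore demonstrate that the pipeline recovers structure it is pointed
at, not clinical-grade performance on real polysomnography: published
MESA-scale results are computed on restricted data and are out of scope
here.

## Numerical choices and edge cases

Zero-phase filtering throughout; anti-aliased decimation; linear
interpolation for RR gaps and for periodogram resampling of interval
series; quantile type 7 for IQRs; sample/approximate entropy with m = 2
and r = 0.2 SD (compiled kernels, self-matches per the standard
definitions); geometric HRV features on the 1/128 s histogram with a
least-squares triangular fit for TINN. Ties in peak pruning keep the
higher peak. All stochastic operations take explicit seeds and restore
the caller's RNG state.

## Worked example

```{r, eval = FALSE}
library(sleepstager)

spec <- sim_cohort_spec(n_participants = 6, night_length_epochs = 240,
                        seed = 42)
cohort <- simulate_cohort(spec)
cfg <- experiment_config(cohort, granularity = 3, combo = "act_hrv_rrv",
                         algorithm = "gboost", budget = 2, seed = 42)
res <- run_experiment(cfg)
res$results$summary
mcc(res$confusion)
```

## Known limitations

The exact published 370/30/60 feature lists live in supplementary material
of the originating study and are not public in machine-readable form; the
shipped manifests match the printed counts, statistic families and window
grids, and users can substitute exact lists since manifests are plain data
frames. The "tpe" search strategy is a budgeted random search rather than
a density-ratio estimator. EDF import is not included; the documented CSV
bundle is the native format.
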