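---
title: "Minimal-sensor screening for REM sleep behaviour disorder: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal-sensor screening for REM sleep behaviour disorder: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

REM sleep behaviour disorder (RBD) is a parasomnia in which the muscle
atonia that normally accompanies REM sleep is lost, so that patients enact
their dreams. It matters clinically because it is one of the strongest known
prodromes of Parkinson's disease and related synucleinopathies. Diagnosis
requires polysomnography (PSG) with expert staging — slow, expensive and
poorly suited to screening at scale. `rbdscreen` implements a fully
automated screening pipeline that needs only three easy-to-apply sensors —
one ECG, one bipolar EOG and one submentalis EMG, no EEG — covering
pre-processing, per-epoch feature extraction, three-state sleep staging
(wake / NREM / REM), subject-level RBD metrics, RBD classification and
Bland-Altman agreement analysis, together with a synthetic cohort generator
that provides ground truth for every stage of the pipeline.

## Signal model and pre-processing

All signals are resampled to 200 Hz. The filter bank is: EOG, a 500th-order
FIR band-pass 0.3–40 Hz; EMG, a 500th-order FIR band-pass 10–95 Hz cascaded
with 500th-order band-stop notches at 48–52 and 58–62 Hz (both European and
North-American mains); ECG, a 10th-order Butterworth band-pass 5–45 Hz.
Three numerical choices deserve note.

* **Zero-phase application.** Every filter is applied forward–backward, so
  features aligned to 30-s epoch boundaries are not skewed by group delay.
  This is realised as convolution with the symmetric kernel $h \ast
  \mathrm{rev}(h)$ using overlap-save FFT blocks, which is exact for the FIR
  designs and, for the Butterworth, uses the impulse response truncated at
  2048 samples (residual below $10^{-30}$, the pole radius being ~0.96).
  Overnight traces filter in well under a second this way.
* **EMG upper edge.** The nominal 10–100 Hz EMG band is infeasible at
  200 Hz sampling (100 Hz is the Nyquist frequency); the upper cutoff is
  capped at 95 Hz.
* **EOG window.** The FIR design window is a free parameter. A
  Hamming-windowed design smears the 0.3 Hz edge over ~1 Hz and leaves slow
  drift (0.05 Hz) attenuated by only ~12 dB after the double pass; the
  rectangular-window design used here rejects it by ~29 dB while holding the
  10 Hz passband within 1 dB, at the cost of benign passband ripple.

## ECG features

QRS complexes are detected with a full Pan–Tompkins implementation:
five-point derivative, squaring, 150-ms moving-window integration, adaptive
signal/noise thresholds, a 200-ms refractory period (within which a
larger-energy candidate replaces the provisional beat, so a noise blip
cannot mask a QRS), T-wave rejection by slope comparison for candidates
within 360 ms, and search-back at half threshold when more than 1.66 times
the running RR average elapses. Detections are localised on the band-passed
signal within ±40 ms, polarity-corrected.

RR intervals outside 300–2000 ms or deviating more than 20% from an
11-beat running median are flagged invalid and excluded from all statistics,
never interpolated. Per 30-s epoch, features are computed from the RR
intervals of a centred 5-minute context window — the standard HRV analysis
span — and every feature is then smoothed by a centred 150-s (5-epoch)
moving average with shrinking windows at the record edges. The bank
comprises 44 features: time-domain (mean/median RR, SDNN, RMSSD, SDSD,
NN50, pNN50 — pNN50 uses the number of valid adjacent pairs as its
denominator), frequency-domain from a 4 Hz cubic-spline tachogram and Welch
periodogram (LF 0.04–0.15 Hz, HF 0.15–0.40 Hz: peaks, powers, total power,
nLF/nHF, LF/HF, and total-power-normalised variants), nonlinear (Poincaré
SD1/SD2; sample and approximate entropy at m = 2, r = 0.2 SD; recurrence
quantification at embedding 3, delay 1, radius 0.2 SD; Teager–Kaiser
energy; DFA slope over 16–64-beat boxes; LZ76 phrase count of the
median-binarised series; auto-mutual-information and autocorrelation at
lags 1–2), Lorenz-plot regularity on a 25-ms lattice (irregularity index,
origin count, compensatory-pause evidence — markers of irregularly
irregular rhythm), waveform shape (zero-crossing statistics, rectified
amplitude moments), tachy/bradycardia flags, and elapsed time from the
first and until the last scored epoch. The entropy/RQA hyper-parameters and
the Lorenz bin width are the conventional literature values; they are
function arguments, not constants, where a user might want to vary them.

Two interpretation notes: the per-epoch-with-context-then-smooth order was
chosen because it yields exactly one feature row per 30-s epoch, which is
what the stager consumes; and the mutual-information/autocorrelation pairs
are implemented at lags 1 and 2, the natural reading of an otherwise
undefined abbreviation set.

## EOG and EMG features

The EOG bank (25 features) targets REM phenomenology: normalised
permutation entropy (order 3, delay 1), maximum absolute peak and coastline
— the three features most diagnostic of rapid eye movements — plus band
powers (absolute and relative over 0.3–2/2–4/4–8/8–13/13–30 Hz), amplitude
percentiles, skewness, kurtosis, zero-crossing rate, half-epoch energy
ratio, 95% spectral edge and Hjorth mobility/complexity. The EMG bank (17
features) targets muscle tone: rectified 75th percentile, spectral entropy,
relative power (epoch band power over the whole-night median), motor
activity (fraction of 1-s mini-epochs whose RMS exceeds twice the night's
5th-percentile RMS — a robust noise-floor reference), RMS, variance,
coastline, percentiles, zero-crossing rate, three band powers, Hjorth
activity/mobility and mean supra-threshold burst duration. Only the named
head of each list is fixed by prior art; the remainder are standard sleep
staging descriptors, and the manifests are exposed so an exact replication
set can be swapped in.

## Staging and detection

Staging is a 500-tree random forest over any sensor combination (A1 = ECG,
B1 = EOG, C1 = EMG, A2/B2/C2 pairs, A3 = all three; EEG-bearing
combinations are explicitly out of scope), with `mtry` = ⌊√M⌋. A quoted
convention of "mtry = M, rounded down" can only refer to the square root —
literal M would reduce the forest to bagged identical-feature trees — but a
literal mode is available in the configuration for strict replication.
Evaluation uses balanced 10-subject folds (5 HC + 5 RBD where available);
no subject ever contributes epochs to both training and test. Metrics are
per-subject one-vs-rest accuracy/sensitivity/specificity/precision/F1
(mean ± SD across subjects) plus three-state Cohen's kappa, reported both
as subject mean and pooled over epochs.

At full overnight scale a single-CPU 500-tree fit on every training epoch
is needlessly slow, so training uses a stratified subsample of 8000 epochs
per fit with terminal node size 20 — evaluation always uses every held-out
epoch. In the sensor-ordering replicate study (C2 vs C1 vs A1, ten seeded
replicates) each replicate is one balanced 10-subject holdout with a
150-tree forest; the kappa ordering is extremely stable in the forest size,
and these sizes keep the whole study inside a desktop-scale run.

Detection operates on 20 subject-level metrics. Thirteen come from the ECG
feature bank conditioned on stage: mean SDNN, LF/HF spectral peaks, sample
entropy, irregularity index and origin count over REM and/or NREM epochs,
the REM/NREM mean-RR ratio, the NREM/REM LF/HF ratio, and the NREM:REM
epoch-count ratio. (The source material is inconsistent about whether 11 or
13 ECG metrics entered the classifier; all 13 are implemented and used by
default.) Seven come from the EMG: the Ferri-style atonia index during REM
(rectified 1-s mini-epoch amplitudes, noise-corrected by subtracting the
surrounding 60-s minimum; the index is the fraction of corrected amplitudes
≤ 1 µV among those ≤ 1 µV or > 2 µV), its NREM/REM ratio, the 10–95 Hz
spectral (fractal) exponent during REM and its NREM/REM ratio, and REM
means of motor activity, burst duration and the rectified 75th percentile.
Subject-level metrics are computed from the *unsmoothed* per-epoch rows,
since the 150-s smoothing exists for the stager, and deliberately mixes
neighbouring stages. A 500-tree forest under the same balanced subject
folds classifies HC vs RBD (RBD is the positive class); sentinel metrics
are median-imputed with training-fold statistics only. The atonia-index
threshold baseline classifies RBD below a threshold tuned on training folds
by balanced accuracy (a fixed literature threshold is a parameter).

Bland-Altman agreement between metrics from manual and automatic staging
uses differences in the direction automatic − manual, limits of agreement
at bias ± 1.96 SD (1.96, not the colloquial 2.0; configurable), a 95%
confidence band for the bias, and a Kolmogorov–Smirnov normality p-value
computed on differences standardised by their own mean and SD (so the
Lilliefors caveat applies; the test is descriptive here).

## The synthetic cohort generator

The generator produces the statistical structure the pipeline assumes,
with ground truth for every intermediate quantity. Its defaults are the
study conditions used by the test-suite and the acceptance script: 20 HC +
20 RBD subjects, 960-epoch (8-h) nights.

* **Hypnogram:** a three-state Markov chain started in wake with stationary
  distribution (W, NREM, REM) = (0.2, 0.6, 0.2) and mean bout lengths of
  5/7.5/5 minutes — coarse but adequate sleep architecture.
* **ECG:** beat-by-beat RR with stage-dependent mean rate (W 70, NREM 60,
  REM 66 bpm), sinusoidal LF (0.1 Hz) and HF (0.25 Hz) modulation whose
  amplitude ratio matches the stage LF/HF target (W 3, NREM 1, REM 3.5 —
  sympathetic REM, parasympathetic NREM) and white jitter sized to the
  stage SDNN (55/45/50 ms); a Mexican-hat QRS template, baseline drift and
  white noise at 15 dB SNR.
* **EOG:** 0.3–8 Hz background plus sawtooth-like deflections (0.4 s,
  100–300 µV) at 4/min during REM and slow rolling movements during wake.
* **EMG:** 10–95 Hz coloured noise (in-band spectral slope −1, so the
  fractal exponent has a stable operating point) with per-second RMS
  envelope 12/5/1 µV for W/NREM/REM.
* **RSWA:** for RBD subjects an effect size in [0, 1] (default 0.8)
  controls intermittent REM tone — tonic segments of mean 20 s at level
  atonic + effect·(NREM − atonic) with duty cycle 0.6·effect, plus phasic
  bursts at 8·effect per minute — and, in the same knob, shrinks the
  REM/NREM HRV contrast toward zero, reflecting the correlated autonomic
  involvement. The intermittent (rather than uniformly elevated) tone is a
  deliberate choice: RSWA is physiologically intermittent, and the atonia
  index's rolling-minimum correction would cancel a uniform elevation
  entirely. A flag decouples the EMG and HRV arms for ablation.

What the generator does **not** emulate: realistic ECG morphology (P/T
waves, ectopy), apnoeas, arousals, movement artefacts, electrode pops,
inter-scorer disagreement, or medication effects. Passing tests therefore
show that the pipeline recovers the structure it models — correctly wired
algorithms with sensible operating points — not that clinical performance
on hospital PSG would match.

## Problem sizes and reproducibility

The acceptance script and the heavier tests run the default cohort (40
subjects × 960 epochs, three 200-Hz channels each: about 700 million
samples end to end) in roughly a quarter of an hour on a single CPU; unit
tests use 1-h nights. All randomness flows from one integer seed through
per-subject derived streams, so any subject can be re-materialised
independently and cohort generation is reproducible to the EDF byte level.

Degenerate inputs follow a sentinel (`NA`) contract throughout: too few
valid RR intervals, absent stages, zero-variance signals and empty epochs
yield missing features rather than errors, and missing features are
median-imputed (training-fold statistics only) at the classifiers.

## Known limitations

* The 25/17-feature EOG/EMG manifests implement every feature named in the
  method this package follows plus standard descriptors; they are not a
  verbatim replication of the original (unpublished) lists.
* The atonia index assumes µV-calibrated EMG; a calibration scale factor is
  exposed for uncalibrated data.
* Bland-Altman here is the classical constant-bias analysis; proportional
  bias (regression-based) variants are out of scope.
* The hypnogram model has no ultradian cycle structure; elapsed-time
  features are therefore weaker discriminators than on real nights.
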