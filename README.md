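# rbdscreen

Fully automated screening for REM sleep behaviour disorder (RBD) from a
minimal polysomnography montage — one ECG, one bipolar EOG and one
submentalis EMG channel, **no EEG**.

RBD is a parasomnia in which the normal muscle atonia of REM sleep is lost
(REM sleep without atonia, RSWA), and it is one of the strongest known
prodromes of Parkinson's disease. Confirming it requires overnight
polysomnography with expert sleep staging, which does not scale to
screening. `rbdscreen` implements the alternative: stage sleep into three
states (W / NREM / REM) automatically from cheap surface sensors, then
quantify RSWA and autonomic dysfunction inside the automatically detected
REM sleep.

The pipeline:

1. **I/O** — EDF signal reading/writing, hypnogram import (R&K and AASM
   vocabularies collapsed to W/NREM/REM: S1–S4/N1–N3 → NREM), 30-s epoch
   grid.
2. **Pre-processing** — resampling to 200 Hz; zero-phase filter bank
   (EOG 0.3–40 Hz FIR, EMG 10–95 Hz FIR + 50/60 Hz notches, ECG 5–45 Hz
   Butterworth).
3. **Features** — Pan–Tompkins QRS detection and a 44-feature per-epoch
   HRV bank (time-domain: SDNN, RMSSD, pNN50, …; spectral from a 4 Hz
   tachogram: LF 0.04–0.15 Hz, HF 0.15–0.40 Hz powers/peaks/ratios;
   nonlinear: sample/approximate entropy, Poincaré SD1/SD2, recurrence
   quantification, DFA, LZ76; Lorenz-plot irregularity), computed over a
   centred 5-min context per 30-s epoch and smoothed with a 150-s moving
   average; 25 EOG features (permutation entropy, max peak, coastline, …)
   and 17 EMG features (rectified 75th percentile, spectral entropy,
   relative power, motor activity, …).
4. **Staging** — a 500-tree random forest (`mtry = ⌊√M⌋`) over any sensor
   combination (A1 = ECG, B1 = EOG, C1 = EMG, C2 = EOG+EMG, A3 = all),
   evaluated with balanced 10-subject-fold cross-validation and
   three-state Cohen's kappa, `kappa = (p_o − p_e)/(1 − p_e)`.
5. **RBD metrics & detection** — 13 stage-conditional ECG metrics and 7
   EMG metrics per subject, headlined by the Ferri-style atonia index
   (fraction of noise-corrected 1-s rectified EMG mini-epochs ≤ 1 µV among
   those ≤ 1 µV or > 2 µV during REM); random-forest HC-vs-RBD
   classification (D1 = ECG, E1 = EMG, D2 = both) plus an atonia-index
   threshold baseline.
6. **Agreement** — Bland-Altman analysis (bias, 1.96 SD limits of
   agreement, bias confidence band, KS normality check) between metrics
   derived from manual and automatic staging.
7. **Synthetic cohorts** — a generator producing overnight recordings with
   Markov hypnograms, stage-dependent HRV, REM-locked EOG deflections and
   stage-dependent EMG tone, where the RBD condition adds intermittent REM
   tone and attenuates the REM/NREM HRV contrast — with ground truth for
   every stage of the pipeline.

## Worked example

```r
library(rbdscreen)

# a small synthetic cohort: 4 HC + 4 RBD subjects, 1-h nights
cfg <- synth_config(n_hc = 4, n_rbd = 4, night_epochs = 120, seed = 11)
cohort <- synth_cohort_features(cfg)

# EOG+EMG staging under balanced subject folds
cv <- subject_fold_cv(cohort$features,
                      staging_config(combination = "C2", seed = 2),
                      fold_size = 4)
cv
#> <staging_cv> C2: kappa 0.873 +/- 0.152 (pooled 0.882)

# subject-level RBD metrics
mets <- cohort_subject_metrics(cohort$caches)
mets[, c("subject_id", "cohort", "AtoniaIndex_REM", "Quantile75_REM")]
#>   subject_id cohort AtoniaIndex_REM Quantile75_REM
#> 1 hc01       HC               1.000           1.24
#> 5 rbd01      RBD              0.669           3.06   # RSWA: atonia lost
#> ...

# RBD detection from the EMG metrics (RBD is the positive class)
detect_cv(mets, detection_config("E1_emg", seed = 4), fold_size = 4)
#> <detection_report> E1_emg (RBD positive):
#>   accuracy 1, sensitivity 1, specificity 1, f1 1

# agreement between metrics from manual vs automatic staging
auto <- cohort_subject_metrics(cohort$caches, cv$predictions)
ba <- agreement_suite(mets, auto)
tidy(ba$AtoniaIndex_REM)
#> bias 0.018, loa [-0.074, 0.110]  # automatic staging barely moves the AI
```

A healthy subject's atonia index sits near 1 (REM chin EMG is silent); the
RBD generator's intermittent REM tone pulls it toward 0.5, and the
detection forest separates the cohorts from exactly that structure.

A thin command-line front end over the same functions lives at
`inst/cli/rbdscreen.R` (`synth`, `stage`, `detect`, `agreement`
subcommands).

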