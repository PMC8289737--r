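# Subject-level RBD detection metrics: stage-conditional summaries of the
# per-epoch ECG feature bank, plus EMG atonia/fractal metrics computed at
# 1-s mini-epoch resolution.

ECG_METRIC_NAMES <- c("RR_REM_Std", "LFpeak_NREM", "LFPeak_REM",
                      "HFpeak_NREM", "HFPeak_REM", "SampEn_REM",
                      "IrrIndex_NREM", "IrrIndex_REM",
                      "OriginCount_NREM", "OriginCount_REM",
                      "RR_Index", "LFHF_Index", "Ratio_NREM")
EMG_METRIC_NAMES <- c("AtoniaIndex_REM", "AtoniaIndexRatio",
                      "FractalExponent_REM", "FractalExponentRatio",
                      "MotorActivity_REM", "StreamDuration_REM",
                      "Quantile75_REM")

#' Names of the subject-level RBD metrics
#'
#' @param modality `"ECG"` (13 metrics) or `"EMG"` (7 metrics).
#' @return character vector.
#' @export
rbd_metric_names <- function(modality = c("ECG", "EMG")) {
  switch(match.arg(modality), ECG = ECG_METRIC_NAMES, EMG = EMG_METRIC_NAMES)
}

stage_mean <- function(x, stage, s) {
  sel <- stage == s & is.finite(x)
  if (!any(sel)) return(NA_real_)
  mean(x[sel])
}

#' Subject-level ECG metrics
#'
#' Stage-conditional means of the per-epoch (unsmoothed) ECG features:
#' SDNN, LF/HF spectral peaks, sample entropy and the Lorenz regularity
#' features averaged over REM and/or NREM epochs, plus three architecture
#' ratios — `RR_Index` (mean RR in REM over NREM), `LFHF_Index` (mean LF/HF
#' in NREM over REM) and `Ratio_NREM` (NREM epoch count over REM epoch
#' count). Metrics whose stage is absent are the missing sentinel.
#'
#' @param ecg_rows per-epoch ECG feature tibble (see [ecg_epoch_matrix()],
#'   `smooth = FALSE`).
#' @param hyp optional [hypnogram()] overriding the rows' `stage` column
#'   (used to recompute metrics under automatic staging).
#' @return named numeric vector of the 13 ECG metrics.
#' @export
ecg_subject_metrics <- function(ecg_rows, hyp = NULL) {
  stage <- if (is.null(hyp)) ecg_rows$stage else
    as.character(hyp$stages)[ecg_rows$epoch + 1L]
  n_rem <- sum(stage == "REM"); n_nrem <- sum(stage == "NREM")
  sm <- function(col, s) stage_mean(ecg_rows[[col]], stage, s)
  rr_rem <- sm("meanRR", "REM"); rr_nrem <- sm("meanRR", "NREM")
  lfhf_rem <- sm("LFHF", "REM"); lfhf_nrem <- sm("LFHF", "NREM")
  c(RR_REM_Std = sm("SDNN", "REM"),
    LFpeak_NREM = sm("LFpeak", "NREM"), LFPeak_REM = sm("LFpeak", "REM"),
    HFpeak_NREM = sm("HFpeak", "NREM"), HFPeak_REM = sm("HFpeak", "REM"),
    SampEn_REM = sm("SampEn", "REM"),
    IrrIndex_NREM = sm("IrrIndex", "NREM"), IrrIndex_REM = sm("IrrIndex", "REM"),
    OriginCount_NREM = sm("OriginCount", "NREM"),
    OriginCount_REM = sm("OriginCount", "REM"),
    RR_Index = if (is.finite(rr_rem) && is.finite(rr_nrem) && rr_nrem > 0)
      rr_rem / rr_nrem else NA_real_,
    LFHF_Index = if (is.finite(lfhf_rem) && is.finite(lfhf_nrem) && lfhf_rem > 0)
      lfhf_nrem / lfhf_rem else NA_real_,
    Ratio_NREM = if (n_rem > 0) n_nrem / n_rem else NA_real_)
}

# rectified 1-s mini-epoch amplitudes with rolling-minimum noise correction
# (the minimum over the surrounding 60 s approximates the local noise floor)
emg_miniepoch_amplitude <- function(trace, scale = 1) {
  fs <- round(trace$rate_hz)
  n_sec <- length(trace$samples) %/% fs
  amp <- colMeans(matrix(abs(trace$samples[seq_len(n_sec * fs)] * scale),
                         nrow = fs))
  corrected <- amp - cpp_rollmin(amp, 30L)
  list(amp = amp, corrected = corrected)
}

sec_stage_labels <- function(hyp, n_sec) {
  lab <- rep(as.character(hyp$stages), each = 30)
  off <- round(hyp$start_offset_s)
  full <- rep("UNSCORED", n_sec)
  take <- min(length(lab), n_sec - off)
  if (take > 0) full[off + seq_len(take)] <- lab[seq_len(take)]
  full
}

atonia_from_corrected <- function(corrected, sec_labels, stage) {
  v <- corrected[sec_labels == stage]
  if (!length(v)) return(NA_real_)
  low <- sum(v <= 1)
  high <- sum(v > 2)          # 1-2 uV band is excluded from the denominator
  if (low + high == 0) return(NA_real_)
  low / (low + high)
}

#' Atonia index
#'
#' Ferri-style REM-atonia quantification: the rectified EMG is averaged in
#' 1-s mini-epochs, noise-corrected by subtracting the minimum mini-epoch
#' amplitude of the surrounding 60 s, and the index is the fraction of
#' mini-epochs at or below 1 uV among those at or below 1 uV or above 2 uV
#' (the 1-2 uV band is excluded), over the requested stage. Near 1 in
#' normal REM atonia; reduced when REM sleep without atonia is present.
#'
#' @param trace filtered EMG [signal_trace()] (uV-calibrated; use `scale`
#'   for uncalibrated data).
#' @param hyp a [hypnogram()].
#' @param stage `"REM"` or `"NREM"`.
#' @param scale amplitude calibration factor applied before thresholding.
#' @return the atonia index in \[0, 1\], or `NA` if the stage is absent.
#' @export
atonia_index <- function(trace, hyp, stage = c("REM", "NREM"), scale = 1) {
  stage <- match.arg(stage)
  stopifnot(trace$modality == "EMG")
  if (!any(as.character(hyp$stages) == stage)) return(NA_real_)
  me <- emg_miniepoch_amplitude(trace, scale)
  atonia_from_corrected(me$corrected, sec_stage_labels(hyp, length(me$corrected)),
                        stage)
}

# per-epoch spectral exponent: slope of log power vs log frequency, 10-95 Hz
emg_epoch_beta <- function(trace, hyp) {
  em <- epoch_matrix_of(trace, hyp)
  if (ncol(em$m) == 0) return(numeric(0))
  sp <- epoch_spectra(em$m, trace$rate_hz)
  sel <- which(sp$freq >= 10 & sp$freq <= 95)
  lf <- log(sp$freq[sel])
  w <- (lf - mean(lf)) / sum((lf - mean(lf))^2)
  as.numeric(w %*% log(pmax(sp$psd[sel, , drop = FALSE], 1e-300)))
}

#' EMG spectral (fractal) exponent for a stage
#'
#' Per-epoch slope of the log-log EMG power spectrum over 10-95 Hz,
#' averaged over the requested stage: ~0 for white (flat-spectrum) EMG,
#' negative for 1/f-shaped activity.
#'
#' @param trace filtered EMG [signal_trace()].
#' @param hyp a [hypnogram()].
#' @param stage `"REM"` or `"NREM"`.
#' @return mean spectral exponent, or `NA` if the stage is absent.
#' @export
fractal_exponent <- function(trace, hyp, stage = c("REM", "NREM")) {
  stage <- match.arg(stage)
  if (!any(as.character(hyp$stages) == stage)) return(NA_real_)
  beta <- emg_epoch_beta(trace, hyp)
  st <- stages_covered(trace, hyp)
  stage_mean(beta, st, stage)
}

#' Subject-level EMG metrics
#'
#' The seven-element EMG metric map: atonia index during REM, atonia index
#' ratio (NREM over REM), spectral/fractal exponent during REM and its
#' NREM-over-REM ratio, and REM means of motor activity, supra-threshold
#' burst (stream) duration and the rectified 75th percentile. Ratio metrics
#' need both stages present; absent stages give sentinels.
#'
#' @param trace filtered EMG [signal_trace()].
#' @param hyp a [hypnogram()].
#' @param emg_rows optional precomputed [emg_epoch_features()] rows (stage
#'   column is ignored in favour of `hyp`).
#' @param scale amplitude calibration factor for the atonia thresholds.
#' @return named numeric vector of the 7 EMG metrics.
#' @export
emg_subject_metrics <- function(trace, hyp, emg_rows = NULL, scale = 1) {
  if (is.null(emg_rows)) emg_rows <- emg_epoch_features(trace, hyp)
  stage <- as.character(hyp$stages)[emg_rows$epoch + 1L]
  me <- emg_miniepoch_amplitude(trace, scale)
  secs <- sec_stage_labels(hyp, length(me$corrected))
  ai_rem <- atonia_from_corrected(me$corrected, secs, "REM")
  ai_nrem <- atonia_from_corrected(me$corrected, secs, "NREM")
  beta <- emg_epoch_beta(trace, hyp)
  b_rem <- stage_mean(beta, stage, "REM")
  b_nrem <- stage_mean(beta, stage, "NREM")
  c(AtoniaIndex_REM = ai_rem,
    AtoniaIndexRatio = if (is.finite(ai_rem) && is.finite(ai_nrem) && ai_rem > 0)
      ai_nrem / ai_rem else NA_real_,
    FractalExponent_REM = b_rem,
    FractalExponentRatio = if (is.finite(b_rem) && is.finite(b_nrem) &&
                               abs(b_rem) > 1e-12)
      b_nrem / b_rem else NA_real_,
    MotorActivity_REM = stage_mean(emg_rows$MotorActivity, stage, "REM"),
    StreamDuration_REM = stage_mean(emg_rows$BurstDuration, stage, "REM"),
    Quantile75_REM = stage_mean(emg_rows$Quantile75, stage, "REM"))
}
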