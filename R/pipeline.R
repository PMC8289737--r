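# End-to-end plumbing: preprocess a recording, extract every per-epoch
# feature bank once, and derive staging rows / subject metrics from the
# cached results so that metrics can be recomputed cheaply under any
# (manual or predicted) hypnogram.

#' Preprocess a recording
#'
#' Resamples every trace to 200 Hz and applies the per-modality filter
#' bank.
#'
#' @param rec a [recording()].
#' @return the recording with filtered 200-Hz traces.
#' @export
preprocess_recording <- function(rec) {
  stopifnot(inherits(rec, "psg_recording"))
  f <- list(ECG = filter_ecg, EOG = filter_eog, EMG = filter_emg)
  rec$traces <- lapply(rec$traces, function(tr)
    f[[tr$modality]](resample_trace(tr, 200)))
  rec
}

#' Extract all per-epoch features for one subject
#'
#' Runs the full feature extraction once: the ECG HRV bank (kept both
#' unsmoothed, for subject-level metrics, and 150-s smoothed, for staging),
#' the EOG and EMG banks, the EMG mini-epoch amplitudes for the atonia
#' index and the per-epoch EMG spectral exponent. The returned cache is all
#' later stages need; the signals can be discarded.
#'
#' @param rec a preprocessed [recording()] with a hypnogram.
#' @param preprocess apply [preprocess_recording()] first.
#' @return an `rbd_subject_features` cache.
#' @export
extract_subject_features <- function(rec, preprocess = TRUE) {
  stopifnot(inherits(rec, "psg_recording"))
  if (is.null(rec$hypnogram)) stop("recording has no hypnogram")
  if (preprocess) rec <- preprocess_recording(rec)
  hyp <- rec$hypnogram
  ecg_raw <- ecg_epoch_matrix(rec$traces$ECG, hyp, smooth = FALSE)
  fc <- ecg_feature_manifest()
  ecg_sm <- ecg_raw
  ecg_sm[fc] <- tibble::as_tibble(smooth_columns(as.matrix(ecg_raw[fc]), 5L))
  emg_rows <- emg_epoch_features(rec$traces$EMG, hyp)
  me <- emg_miniepoch_amplitude(rec$traces$EMG)
  structure(list(subject_id = rec$subject_id, cohort = rec$cohort,
                 hypnogram = hyp,
                 ecg = ecg_raw, ecg_smooth = ecg_sm,
                 eog = eog_epoch_features(rec$traces$EOG, hyp),
                 emg = emg_rows,
                 emg_corrected = me$corrected,
                 emg_beta = attr(emg_rows, "beta")),
            class = "rbd_subject_features")
}

#' @export
print.rbd_subject_features <- function(x, ...) {
  cat(sprintf("<rbd_subject_features> %s [%s]: %d epochs\n", x$subject_id,
              ifelse(is.na(x$cohort), "?", x$cohort), nrow(x$ecg)))
  invisible(x)
}

#' Staging feature rows from a subject cache
#'
#' One row per epoch with modality-prefixed columns (`ecg_` smoothed HRV
#' bank, `eog_`, `emg_`) ready for [train_stager()] / [subject_fold_cv()].
#'
#' @param cache an `rbd_subject_features`.
#' @return epoch-feature tibble.
#' @export
staging_rows <- function(cache) {
  stopifnot(inherits(cache, "rbd_subject_features"))
  pre <- function(df, p) {
    fc <- setdiff(names(df), ID_COLS)
    stats::setNames(df[fc], paste0(p, "_", fc))
  }
  dplyr::bind_cols(
    tibble::tibble(subject_id = cache$subject_id, cohort = cache$cohort,
                   epoch = cache$ecg$epoch, stage = cache$ecg$stage),
    pre(cache$ecg_smooth, "ecg"), pre(cache$eog, "eog"), pre(cache$emg, "emg"))
}

emg_metrics_from_cache <- function(cache, hyp) {
  stage <- as.character(hyp$stages)[cache$emg$epoch + 1L]
  secs <- sec_stage_labels(hyp, length(cache$emg_corrected))
  ai_rem <- atonia_from_corrected(cache$emg_corrected, secs, "REM")
  ai_nrem <- atonia_from_corrected(cache$emg_corrected, secs, "NREM")
  b_rem <- stage_mean(cache$emg_beta, stage, "REM")
  b_nrem <- stage_mean(cache$emg_beta, stage, "NREM")
  c(AtoniaIndex_REM = ai_rem,
    AtoniaIndexRatio = if (is.finite(ai_rem) && is.finite(ai_nrem) && ai_rem > 0)
      ai_nrem / ai_rem else NA_real_,
    FractalExponent_REM = b_rem,
    FractalExponentRatio = if (is.finite(b_rem) && is.finite(b_nrem) &&
                               abs(b_rem) > 1e-12) b_nrem / b_rem else NA_real_,
    MotorActivity_REM = stage_mean(cache$emg$MotorActivity, stage, "REM"),
    StreamDuration_REM = stage_mean(cache$emg$BurstDuration, stage, "REM"),
    Quantile75_REM = stage_mean(cache$emg$Quantile75, stage, "REM"))
}

#' Subject metric row from a cache
#'
#' Computes the 13 ECG + 7 EMG subject-level metrics under the given
#' hypnogram (defaulting to the cache's manual hypnogram; pass a predicted
#' hypnogram to evaluate fully automatic screening).
#'
#' @param cache an `rbd_subject_features`.
#' @param hyp optional [hypnogram()] override.
#' @return one-row tibble: `subject_id`, `cohort`, 20 metric columns.
#' @export
subject_metric_row <- function(cache, hyp = NULL) {
  stopifnot(inherits(cache, "rbd_subject_features"))
  if (is.null(hyp)) hyp <- cache$hypnogram
  em <- ecg_subject_metrics(cache$ecg, hyp)
  gm <- emg_metrics_from_cache(cache, hyp)
  dplyr::bind_cols(tibble::tibble(subject_id = cache$subject_id,
                                  cohort = cache$cohort),
                   tibble::as_tibble_row(c(em, gm)))
}

#' Generate a synthetic cohort and extract all features
#'
#' Subjects are generated, preprocessed and reduced to their feature caches
#' one at a time, so the memory footprint stays at a single night of
#' signals.
#'
#' @param cfg a [synth_config()].
#' @param progress print one line per subject.
#' @return list with `features` (stacked [staging_rows()] for the whole
#'   cohort), `caches` (named list of subject caches) and `manifest`.
#' @export
synth_cohort_features <- function(cfg = synth_config(), progress = FALSE) {
  ids <- c(sprintf("hc%02d", seq_len(cfg$n_hc)),
           sprintf("rbd%02d", seq_len(cfg$n_rbd)))
  cohorts <- rep(c("HC", "RBD"), c(cfg$n_hc, cfg$n_rbd))
  manifest <- tibble::tibble(subject_id = ids, cohort = cohorts,
                             seed = derive_seed(cfg$seed, seq_along(ids), 9))
  caches <- vector("list", length(ids))
  names(caches) <- ids
  for (i in seq_along(ids)) {
    if (progress) message(sprintf("[%d/%d] %s", i, length(ids), ids[i]))
    sub <- generate_recording(cfg, ids[i], cohorts[i], seed = manifest$seed[i])
    caches[[i]] <- extract_subject_features(sub$recording)
  }
  list(features = dplyr::bind_rows(lapply(caches, staging_rows)),
       caches = caches, manifest = manifest)
}

#' Subject metric table for a cohort
#'
#' @param caches named list of `rbd_subject_features`.
#' @param hypnograms optional named list of [hypnogram()] overrides (e.g.
#'   the predictions of [subject_fold_cv()]); subjects without an entry use
#'   their manual hypnogram.
#' @return tibble with one row per subject.
#' @export
cohort_subject_metrics <- function(caches, hypnograms = NULL) {
  dplyr::bind_rows(lapply(caches, function(cc)
    subject_metric_row(cc, hyp = hypnograms[[cc$subject_id]])))
}
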