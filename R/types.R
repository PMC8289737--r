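#' Construct a single-channel signal trace
#'
#' A `psg_trace` holds one channel's uniformly sampled signal in physical
#' units (microvolts for EOG/EMG, whatever the source header declares for
#' ECG), together with its sampling rate and modality tag. Non-finite samples
#' are repaired by linear interpolation and reported with a warning; they are
#' never silently propagated into downstream features.
#'
#' @param samples numeric vector of samples in physical units.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param modality one of `"ECG"`, `"EOG"`, `"EMG"`.
#' @param label free-text channel name (defaults to the modality).
#' @return an object of class `psg_trace`.
#' @export
signal_trace <- function(samples, rate_hz, modality = c("ECG", "EOG", "EMG"),
                         label = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0)
  samples <- as.numeric(samples)
  bad <- !is.finite(samples)
  if (any(bad)) {
    warning(sprintf("%d non-finite sample(s) in %s trace repaired by interpolation",
                    sum(bad), modality))
    if (all(bad)) {
      samples[] <- 0
    } else {
      idx <- seq_along(samples)
      samples[bad] <- stats::approx(idx[!bad], samples[!bad], xout = idx[bad],
                                    rule = 2)$y
    }
  }
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         modality = modality,
         label = if (is.null(label)) modality else as.character(label)),
    class = "psg_trace"
  )
}

#' @export
print.psg_trace <- function(x, ...) {
  cat(sprintf("<psg_trace> %s (%s): %d samples @ %g Hz (%.1f s)\n",
              x$label, x$modality, length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz))
  invisible(x)
}

#' @export
length.psg_trace <- function(x) length(x$samples)

trace_duration_s <- function(trace) length(trace$samples) / trace$rate_hz

#' Construct a hypnogram
#'
#' Per-epoch sleep-stage labels on a fixed 30-s grid over the three-state
#' alphabet W/NREM/REM plus UNSCORED. `start_offset_s` places epoch 0 relative
#' to the recording start (technicians typically begin scoring around
#' lights-off, which need not coincide with the start of the signal file).
#'
#' @param stages character vector (or factor) over
#'   `c("W","NREM","REM","UNSCORED")`.
#' @param epoch_s epoch length in seconds; fixed at 30.
#' @param start_offset_s offset of epoch 0 from recording start, seconds.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30, start_offset_s = 0) {
  if (epoch_s != 30) stop("epoch_s is fixed at 30 s")
  stages <- as.character(stages)
  if (length(stages) > 0 && !all(stages %in% STAGES4)) {
    bad <- setdiff(unique(stages), STAGES4)
    stop("stages outside the W/NREM/REM/UNSCORED alphabet: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(stages = factor(stages, levels = STAGES4), epoch_s = 30,
         start_offset_s = as.numeric(start_offset_s)),
    class = "hypnogram"
  )
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(x$stages)
  cat(sprintf("<hypnogram> %d x 30-s epochs (offset %g s): %s\n",
              length(x$stages), x$start_offset_s,
              paste(sprintf("%s=%d", names(tb), tb), collapse = " ")))
  invisible(x)
}

#' @export
as_tibble.hypnogram <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$stages) - 1L,
    onset_s = x$start_offset_s + (seq_along(x$stages) - 1L) * 30,
    stage = as.character(x$stages)
  )
}

#' Construct a multi-channel recording
#'
#' Bundles at most one trace per modality with an optional hypnogram and a
#' subject/cohort annotation. Traces with unequal durations are trimmed to
#' the shortest common span (the documented alignment rule) with a warning
#' when more than one second is lost.
#'
#' @param subject_id subject identifier.
#' @param traces named list of [signal_trace()] objects, names irrelevant
#'   (modalities are read from the traces).
#' @param hypnogram optional [hypnogram()].
#' @param cohort optional cohort label, `"HC"` or `"RBD"`.
#' @return an object of class `psg_recording`.
#' @export
recording <- function(subject_id, traces, hypnogram = NULL, cohort = NA_character_) {
  stopifnot(is.list(traces), length(traces) >= 1)
  mods <- vapply(traces, function(tr) tr$modality, character(1))
  if (anyDuplicated(mods)) stop("at most one trace per modality")
  names(traces) <- mods
  if (!is.na(cohort) && !cohort %in% c("HC", "RBD"))
    stop("cohort must be HC or RBD (or NA)")
  durs <- vapply(traces, trace_duration_s, numeric(1))
  if (diff(range(durs)) > 0) {
    if (diff(range(durs)) > 1)
      warning(sprintf("traces trimmed to common span (%.1f s lost)",
                      diff(range(durs))))
    dmin <- min(durs)
    traces <- lapply(traces, function(tr) {
      n <- floor(dmin * tr$rate_hz)
      tr$samples <- tr$samples[seq_len(n)]
      tr
    })
  }
  structure(
    list(subject_id = as.character(subject_id), cohort = cohort,
         traces = traces, hypnogram = hypnogram),
    class = "psg_recording"
  )
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %s [%s]: %s%s\n", x$subject_id,
              ifelse(is.na(x$cohort), "?", x$cohort),
              paste(names(x$traces), collapse = "+"),
              if (is.null(x$hypnogram)) "" else
                sprintf(", %d scored epochs", length(x$hypnogram))))
  invisible(x)
}
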