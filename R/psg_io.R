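#' Map heterogeneous sleep-stage labels to the three-state alphabet
#'
#' Collapses R&K and AASM stage vocabularies onto W/NREM/REM: S1-S4 and
#' N1-N3 become NREM, R/REM stay REM, W/Wake/0 become W, and anything else
#' (movement time, artefact codes, unknown dialects) becomes UNSCORED.
#' The mapping is total, case-insensitive and idempotent on its own outputs.
#'
#' @param label character vector of raw stage labels.
#' @return character vector over `c("W","NREM","REM","UNSCORED")`.
#' @export
#' @examples
#' map_to_three_state(c("N2", "S4", "rem", "W", "MOVEMENT"))
map_to_three_state <- function(label) {
  lab <- toupper(trimws(as.character(label)))
  out <- rep("UNSCORED", length(lab))
  out[lab %in% c("S1", "S2", "S3", "S4", "N1", "N2", "N3", "NREM")] <- "NREM"
  out[lab %in% c("R", "REM")] <- "REM"
  out[lab %in% c("W", "WAKE", "0")] <- "W"
  out
}

#' Read a hypnogram file
#'
#' Three dialects are supported: `"csv"` (the package's interchange dialect,
#' header `epoch,stage`), `"capstyle"` (one raw stage label per line, no
#' header) and `"massstyle"` (comma-separated `onset_s,stage` rows whose
#' onsets must advance in 30-s steps). Raw labels are collapsed through
#' [map_to_three_state()]; labels that fall through to UNSCORED trigger one
#' summary warning.
#'
#' @param path file path.
#' @param dialect one of `"csv"`, `"capstyle"`, `"massstyle"`.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("csv", "capstyle", "massstyle")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty hypnogram file: ", path)
  offset <- 0
  raw <- switch(dialect,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (!all(c("epoch", "stage") %in% names(df)))
        stop("csv dialect requires header 'epoch,stage'")
      df$stage[order(df$epoch)]
    },
    capstyle = trimws(lines),
    massstyle = {
      parts <- strsplit(lines, ",")
      onset <- as.numeric(vapply(parts, `[[`, character(1), 1L))
      stg <- trimws(vapply(parts, `[[`, character(1), 2L))
      if (length(onset) > 1 && any(abs(diff(onset) - 30) > 1e-6))
        stop("massstyle onsets must advance in 30-s steps ",
             "(no resampling rule is defined for other epoch durations)")
      offset <- onset[1]
      stg
    }
  )
  mapped <- map_to_three_state(raw)
  n_un <- sum(mapped == "UNSCORED" & toupper(trimws(raw)) != "UNSCORED")
  if (n_un > 0)
    warning(sprintf("%d label(s) outside the mapping table set to UNSCORED", n_un))
  hypnogram(mapped, start_offset_s = offset)
}

#' Write a hypnogram in the interchange CSV dialect
#'
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.csv(
    data.frame(epoch = seq_along(hyp$stages) - 1L,
               stage = as.character(hyp$stages)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format) I/O. Fixed-layout ASCII header, int16 LE data
# records; physical calibration via (physical, digital) min/max per signal.

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording to an EDF file
#'
#' Signals are quantised to 16-bit integers over a symmetric physical range
#' covering each trace; the quantisation step is therefore range/65535.
#' Record duration is 1 s, so every sampling rate must be a whole number of
#' samples per second. Trailing samples beyond the last whole second are
#' dropped.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  traces <- rec$traces
  rates <- vapply(traces, function(tr) tr$rate_hz, numeric(1))
  if (any(abs(rates - round(rates)) > 1e-9))
    stop("write_edf requires integer sampling rates (1-s records)")
  n_rec <- min(vapply(traces, function(tr)
    floor(length(tr$samples) / tr$rate_hz), numeric(1)))
  ns <- length(traces)
  con <- file(path, "wb")
  on.exit(close(con))

  phys_max <- vapply(traces, function(tr) {
    m <- max(abs(tr$samples), 1e-12)
    m * (1 + 1e-6)
  }, numeric(1))

  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(ifelse(is.na(rec$cohort), "X", rec$cohort), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4),
    paste(vapply(traces, function(tr) edf_pad(tr$label, 16), character(1)), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(vapply(traces, function(tr)
      edf_pad(ifelse(tr$modality == "ECG", "mV", "uV"), 8), character(1)), collapse = ""),
    paste(vapply(seq_len(ns), function(i) edf_pad(sprintf("%.6g", -phys_max[i]), 8), character(1)), collapse = ""),
    paste(vapply(seq_len(ns), function(i) edf_pad(sprintf("%.6g", phys_max[i]), 8), character(1)), collapse = ""),
    paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(vapply(traces, function(tr) edf_pad(tr$rate_hz, 8), character(1)), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  # digital conversion, all records at once then interleave per record
  dig <- lapply(seq_len(ns), function(i) {
    x <- traces[[i]]$samples[seq_len(n_rec * rates[i])]
    g <- (2 * phys_max[i]) / 65535
    d <- round((x + phys_max[i]) / g) - 32768
    as.integer(pmin(32767, pmax(-32768, d)))
  })
  spr <- as.integer(rates)
  out <- integer(sum(spr) * n_rec)
  pos <- 0L
  offs <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- dig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])]
      out[(pos + 1L):(pos + spr[i])] <- seg
      pos <- pos + spr[i]
    }
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' @param path EDF file path.
#' @param channel_map named character vector mapping modality to the channel
#'   label in the file, e.g. `c(ECG = "ECG", EOG = "EOG", EMG = "EMG-subm")`.
#'   Matching is exact on trimmed labels.
#' @param subject_id subject identifier; default takes the EDF patient field,
#'   falling back to the file name.
#' @param cohort optional cohort label.
#' @return a [recording()] with one trace per requested modality.
#' @export
read_edf <- function(path, channel_map = c(ECG = "ECG", EOG = "EOG", EMG = "EMG"),
                     subject_id = NULL, cohort = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("corrupt EDF header (version field '", ver, "')")
  patient <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header (signal count)")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                    # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)                    # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  seek(con, hdr_bytes)

  want <- match(trimws(channel_map), labels)
  if (anyNA(want))
    stop("channel(s) not found: ",
         paste(channel_map[is.na(want)], collapse = ", "),
         "; available: ", paste(labels, collapse = ", "))

  raw16 <- readBin(con, integer(), n = sum(spr) * n_rec, size = 2L,
                   endian = "little")
  offs <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  traces <- lapply(seq_along(want), function(k) {
    i <- want[k]
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]),
                           (seq_len(n_rec) - 1L) * rec_len, `+`))
    d <- raw16[idx]
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    x <- (d - dmin[i]) * g + pmin[i]
    signal_trace(x, rate_hz = spr[i] / dur,
                 modality = names(channel_map)[k], label = labels[i])
  })
  if (is.null(subject_id))
    subject_id <- if (nzchar(patient)) patient else
      sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  recording(subject_id, traces, cohort = cohort)
}

#' Resample a trace to a target rate
#'
#' Rational-ratio polyphase resampling with an anti-aliasing FIR low-pass
#' when the rate decreases. Duration is preserved to within one sample
#' period; a trace already at the target rate is returned unchanged.
#'
#' @param trace a [signal_trace()].
#' @param target_hz target sampling rate (> 0).
#' @return a [signal_trace()] at `target_hz`.
#' @export
resample_trace <- function(trace, target_hz) {
  stopifnot(inherits(trace, "psg_trace"))
  if (!is.numeric(target_hz) || length(target_hz) != 1 || target_hz <= 0)
    stop("target_hz must be a positive scalar")
  if (abs(target_hz - trace$rate_hz) < 1e-9) return(trace)
  fr <- rational_approx(target_hz / trace$rate_hz)
  y <- signal::resample(trace$samples, p = fr[1], q = fr[2])
  n_target <- round(length(trace$samples) * target_hz / trace$rate_hz)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(y[length(y)], n_target - length(y)))
  signal_trace(y, target_hz, trace$modality, trace$label)
}

# small rational approximation (continued fractions), max denominator 1024
rational_approx <- function(x, max_den = 1024) {
  a0 <- floor(x); p0 <- 1; q0 <- 0; p1 <- a0; q1 <- 1; r <- x - a0
  while (q1 < max_den && r > 1e-12) {
    x <- 1 / r; a <- floor(x); r <- x - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}

#' Epoch slice table for a trace under a hypnogram
#'
#' Returns one row per 30-s epoch with half-open, 0-based sample ranges
#' `[from, to)` of exactly `30 * rate_hz` samples, aligned to the
#' hypnogram's `start_offset_s`. A trailing epoch not fully covered by the
#' trace is dropped with a warning; a hypnogram extending more than one
#' epoch beyond the trace is an error.
#'
#' @param trace a [signal_trace()].
#' @param hyp a [hypnogram()].
#' @return a tibble with columns `epoch`, `from`, `to`, `stage`.
#' @export
epoch_slices <- function(trace, hyp) {
  stopifnot(inherits(trace, "psg_trace"), inherits(hyp, "hypnogram"))
  spe <- round(30 * trace$rate_hz)
  n_ep <- length(hyp$stages)
  if (n_ep == 0)
    return(tibble::tibble(epoch = integer(), from = integer(),
                          to = integer(), stage = character()))
  off <- round(hyp$start_offset_s * trace$rate_hz)
  from <- off + (seq_len(n_ep) - 1L) * spe
  to <- from + spe
  n <- length(trace$samples)
  covered <- to <= n
  if (sum(!covered) > 1)
    stop("hypnogram extends more than one epoch beyond the trace")
  if (any(!covered))
    warning("trailing partial epoch dropped (trace ends before epoch boundary)")
  tibble::tibble(epoch = which(covered) - 1L, from = as.integer(from[covered]),
                 to = as.integer(to[covered]),
                 stage = as.character(hyp$stages)[covered])
}

# stage label per epoch restricted to epochs fully covered by a trace
stages_covered <- function(trace, hyp) {
  sl <- epoch_slices(trace, hyp)
  sl$stage
}
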