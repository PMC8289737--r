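# Heart-rate-variability feature bank. Public operations take an
# `rr_series` tibble (from rr_from_peaks()); hot inner paths operate on bare
# vectors so that the per-epoch sweep over a full night stays fast.

hrv_na <- function(names) stats::setNames(rep(NA_real_, length(names)), names)

TD_NAMES <- c("meanRR", "medianRR", "SDNN", "RMSSD", "SDSD", "NN50", "pNN50")
FD_NAMES <- c("LFpeak", "HFpeak", "totalPower", "LFpower", "HFpower",
              "nLF", "nHF", "LFHF", "LFpower_n", "HFpower_n")
NL_NAMES <- c("PoincareSD1", "PoincareSD2", "SampEn", "ApEn",
              "RecurrenceRate", "DET", "ENTR", "L", "TKEO", "DFAa2", "LZ",
              "PD", "BD", "PDa", "BDa")
REG_NAMES <- c("IrrIndex", "OriginCount", "PACEv")
SHAPE_NAMES <- c("ZCI", "mZCI", "AmpVarsqi", "Ampstdsqi", "AmpMean")

#' ECG staging feature manifest
#'
#' The ordered names of the per-epoch ECG feature set: time-domain,
#' frequency-domain (with normalised variants), nonlinear, Lorenz-plot
#' regularity, waveform shape, rate flags and elapsed-time features.
#'
#' @return character vector of feature names.
#' @export
ecg_feature_manifest <- function() {
  c(TD_NAMES, FD_NAMES, NL_NAMES, REG_NAMES, SHAPE_NAMES,
    "Tachy", "Brady", "HoursRec", "HoursRecEnd")
}

# --- time domain -----------------------------------------------------------

td_hrv_vec <- function(rr, valid) {
  x <- rr[valid]
  if (length(x) < 2) return(hrv_na(TD_NAMES))
  adj <- valid[-length(valid)] & valid[-1]
  d <- (rr[-1] - rr[-length(rr)])[adj]
  nn50 <- if (length(d)) sum(abs(d) > 50) else NA_real_
  c(meanRR = mean(x), medianRR = stats::median(x), SDNN = stats::sd(x),
    RMSSD = if (length(d)) sqrt(mean(d^2)) else NA_real_,
    SDSD = if (length(d) >= 2) stats::sd(d) else NA_real_,
    NN50 = as.numeric(nn50),
    pNN50 = if (length(d)) nn50 / length(d) else NA_real_)
}

#' Time-domain HRV features
#'
#' Textbook definitions over the valid intervals of an RR series: mean and
#' median RR, SDNN, RMSSD, SDSD, NN50 and pNN50. Differences are taken only
#' between adjacent valid intervals; pNN50 is NN50 over the number of valid
#' adjacent pairs. Fewer than two valid intervals gives the missing
#' sentinel (`NA`) for every feature.
#'
#' @param rr an `rr_series` tibble.
#' @return named numeric vector.
#' @export
time_domain_hrv <- function(rr) td_hrv_vec(rr$rr_ms, rr$valid)

# --- frequency domain ------------------------------------------------------

# Welch periodogram, Hann window, 50% overlap, one-sided, unit**2/Hz
welch_psd <- function(x, fs, nseg = 256L) {
  n <- length(x)
  nseg <- min(nseg, 2^floor(log2(n)))
  if (nseg < 32) return(NULL)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  step <- nseg %/% 2L
  starts <- seq(1L, n - nseg + 1L, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * fs * sum(w^2))
  half <- nseg %/% 2L
  list(freq = (seq_len(half) - 1) * fs / nseg,
       psd = 2 * psd[seq_len(half)])
}

band_power <- function(sp, lo, hi) {
  sel <- sp$freq >= lo & sp$freq < hi
  if (!any(sel)) return(0)
  sum(sp$psd[sel]) * (sp$freq[2] - sp$freq[1])
}

band_peak <- function(sp, lo, hi) {
  sel <- which(sp$freq >= lo & sp$freq < hi)
  if (!length(sel)) return(NA_real_)
  sp$freq[sel[which.max(sp$psd[sel])]]
}

fd_from_tach <- function(tach, fs = 4) {
  sp <- welch_psd(tach, fs)
  if (is.null(sp)) return(hrv_na(FD_NAMES))
  lf <- band_power(sp, 0.04, 0.15)
  hf <- band_power(sp, 0.15, 0.40)
  tot <- band_power(sp, 1 / 300, 0.40)
  c(LFpeak = band_peak(sp, 0.04, 0.15), HFpeak = band_peak(sp, 0.15, 0.40),
    totalPower = tot, LFpower = lf, HFpower = hf,
    nLF = if (lf + hf > 0) lf / (lf + hf) else NA_real_,
    nHF = if (lf + hf > 0) hf / (lf + hf) else NA_real_,
    LFHF = if (hf > 0) lf / hf else NA_real_,
    LFpower_n = if (tot > 0) lf / tot else NA_real_,
    HFpower_n = if (tot > 0) hf / tot else NA_real_)
}

# cubic interpolation of the RR tachogram onto an even 4 Hz grid
tachogram_4hz <- function(onset_s, rr_ms, valid, from = NULL, to = NULL,
                          fs = 4) {
  t <- onset_s[valid]; v <- rr_ms[valid]
  if (length(t) < 4) return(NULL)
  keep <- c(TRUE, diff(t) > 0)
  t <- t[keep]; v <- v[keep]
  if (is.null(from)) from <- t[1]
  if (is.null(to)) to <- t[length(t)]
  grid <- seq(from, to, by = 1 / fs)
  if (length(grid) < 8) return(NULL)
  y <- stats::spline(t, v, xout = grid, method = "natural")$y
  list(t = grid, y = y)
}

#' Frequency-domain HRV features
#'
#' The RR tachogram is cubic-spline resampled to an even 4 Hz grid and a
#' Hann-window Welch periodogram is computed. LF is 0.04-0.15 Hz, HF is
#' 0.15-0.40 Hz; `nLF`/`nHF` normalise by LF+HF, the `_n` variants by total
#' power, and `LFHF` is the LF/HF ratio. At least 60 s of valid RR coverage
#' is required, otherwise every feature is the missing sentinel.
#'
#' @param rr an `rr_series` tibble (typically restricted to a 5-min window).
#' @param window_s nominal analysis window, seconds (used only for the
#'   coverage check denominator).
#' @return named numeric vector.
#' @export
freq_domain_hrv <- function(rr, window_s = 300) {
  if (sum(rr$rr_ms[rr$valid]) / 1000 < 60) return(hrv_na(FD_NAMES))
  tach <- tachogram_4hz(rr$onset_s, rr$rr_ms, rr$valid)
  if (is.null(tach)) return(hrv_na(FD_NAMES))
  fd_from_tach(tach$y)
}

# --- nonlinear -------------------------------------------------------------

auto_mutual_info <- function(x, lag, bins = 8L) {
  n <- length(x) - lag
  if (n < bins * 2) return(NA_real_)
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3) return(0)  # (near-)constant series carries no information
  b <- findInterval(x, br[-c(1, length(br))]) + 1L
  nb <- length(br) - 1L
  i <- b[seq_len(n)]; j <- b[seq_len(n) + lag]
  joint <- tabulate(i + nb * (j - 1L), nbins = nb * nb) / n
  pi_ <- tabulate(i, nbins = nb) / n
  pj <- tabulate(j, nbins = nb) / n
  pp <- outer(pi_, pj)
  sel <- joint > 0
  sum(joint[sel] * log(joint[sel] / pp[sel]))
}

acf_lag <- function(x, lag) {
  n <- length(x)
  if (n <= lag + 1) return(NA_real_)
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) return(NA_real_)
  sum(xc[seq_len(n - lag)] * xc[seq_len(n - lag) + lag]) / den
}

dfa_slope <- function(x, sizes = c(16, 20, 25, 32, 40, 50, 64)) {
  n <- length(x)
  sizes <- sizes[sizes <= n %/% 2]
  if (length(sizes) < 3) return(NA_real_)
  y <- cumsum(x - mean(x))
  fl <- vapply(sizes, function(s) {
    k <- n %/% s
    m <- matrix(y[seq_len(k * s)], nrow = s)
    t <- seq_len(s)
    tc <- t - mean(t)
    stt <- sum(tc^2)
    beta <- colSums(m * tc) / stt
    alpha <- colMeans(m)
    res <- m - outer(tc, beta) - rep(alpha, each = s)
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- fl > 0
  if (sum(ok) < 3) return(NA_real_)
  stats::coef(stats::lm.fit(cbind(1, log(sizes[ok])), log(fl[ok])))[2]
}

nl_hrv_vec <- function(rr, valid) {
  x <- rr[valid]
  n <- length(x)
  if (n < 10) return(hrv_na(NL_NAMES))
  adj <- valid[-length(valid)] & valid[-1]
  d <- (rr[-1] - rr[-length(rr)])[adj]
  sd1 <- if (length(d) >= 2) sqrt(stats::var(d) / 2) else NA_real_
  sd2 <- if (length(d) >= 2)
    sqrt(max(2 * stats::var(x) - stats::var(d) / 2, 0)) else NA_real_
  s <- stats::sd(x)
  if (s == 0) {
    ent <- c(SampEn = 0, ApEn = 0)
    rqa <- c(RecurrenceRate = 1, DET = 1, ENTR = 0,
             L = (n - 2))  # one long diagonal per offset; mean length ~ n
    lz <- 1
  } else {
    r <- 0.2 * s
    sa <- cpp_sampen_apen(x, 2L, r)
    ent <- c(SampEn = sa[1], ApEn = sa[2])
    q <- cpp_rqa(x, 3L, 1L, r, 1L)
    rqa <- c(RecurrenceRate = q[1], DET = q[2], ENTR = q[3], L = q[4])
    lz <- cpp_lz76(as.integer(x > stats::median(x)))
  }
  tkeo <- mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
  c(PoincareSD1 = sd1, PoincareSD2 = sd2, ent, rqa,
    TKEO = tkeo, DFAa2 = dfa_slope(x), LZ = as.numeric(lz),
    PD = auto_mutual_info(x, 1L), BD = auto_mutual_info(x, 2L),
    PDa = acf_lag(x, 1L), BDa = acf_lag(x, 2L))
}

#' Nonlinear HRV features
#'
#' Poincare SD1/SD2, sample and approximate entropy (m = 2, r = 0.2 SD),
#' recurrence quantification (embedding m = 3, delay 1, radius 0.2 SD):
#' recurrence rate, determinism, diagonal-length Shannon entropy and mean
#' diagonal length; mean Teager-Kaiser energy; detrended-fluctuation slope
#' over 16-64-beat boxes; Lempel-Ziv (LZ76) phrase count of the
#' median-binarised series; auto-mutual-information at lags 1 and 2 (PD,
#' BD) and autocorrelation at lags 1 and 2 (PDa, BDa). Fewer than 10 valid
#' intervals gives the missing sentinel.
#'
#' @param rr an `rr_series` tibble.
#' @return named numeric vector.
#' @export
nonlinear_hrv <- function(rr) nl_hrv_vec(rr$rr_ms, rr$valid)

# --- Lorenz-plot regularity ------------------------------------------------

reg_vec <- function(rr, valid, bin_ms = 25) {
  if (sum(valid) < 3) return(hrv_na(REG_NAMES))
  adj <- valid[-length(valid)] & valid[-1]
  d_all <- rr[-1] - rr[-length(rr)]
  # consecutive difference pairs (needs runs of three valid intervals)
  tri <- adj[-length(adj)] & adj[-1]
  if (!any(tri)) return(c(IrrIndex = 0, OriginCount = 0, PACEv = 0))
  d1 <- d_all[-length(d_all)][tri]
  d2 <- d_all[-1][tri]
  f1 <- floor((d1 + bin_ms / 2) / bin_ms)
  f2 <- floor((d2 + bin_ms / 2) / bin_ms)
  at_origin <- f1 == 0 & f2 == 0
  occupied <- unique(paste(f1[!at_origin], f2[!at_origin]))
  c(IrrIndex = length(occupied),
    OriginCount = sum(at_origin),
    PACEv = sum(d1 < -50 & d2 > 50))
}

#' Lorenz-plot heart-beat regularity features
#'
#' Successive RR differences are plotted as (dRR(i-1), dRR(i)) and binned on
#' a 25-ms lattice centred on the origin. `OriginCount` counts points in the
#' origin bin, `IrrIndex` the number of occupied non-origin bins (irregularly
#' irregular rhythm scatters points widely), and `PACEv` counts premature
#' beat signatures: a shortening below -50 ms followed by a compensatory
#' lengthening above +50 ms.
#'
#' @param rr an `rr_series` tibble.
#' @param bin_ms Lorenz lattice bin width, ms.
#' @return named numeric vector.
#' @export
regularity_features <- function(rr, bin_ms = 25) reg_vec(rr$rr_ms, rr$valid, bin_ms)

# --- waveform shape, rate flags, elapsed time ------------------------------

shape_vec <- function(x, fs) {
  s <- sign(x)
  cross <- which(s[-length(s)] * s[-1] < 0)
  zci <- length(cross) / (length(x) / fs)
  mzci <- if (length(cross) >= 2) mean(diff(cross)) / fs else NA_real_
  ax <- abs(x)
  c(ZCI = zci, mZCI = mzci, AmpVarsqi = stats::var(ax),
    Ampstdsqi = stats::sd(ax), AmpMean = mean(ax))
}

#' ECG waveform shape features for one epoch
#'
#' Zero-crossing rate (crossings per second), mean inter-crossing interval,
#' and mean/SD/variance of the rectified filtered amplitude.
#'
#' @param x numeric vector, one 30-s epoch of filtered ECG.
#' @param fs sampling rate in Hz.
#' @return named numeric vector.
#' @export
ecg_shape_features <- function(x, fs = 200) shape_vec(x, fs)

#' Tachycardia / bradycardia flags
#'
#' Mean heart rate over the epoch's five-minute RR context: above 100 bpm
#' sets `Tachy`, below 60 bpm sets `Brady`.
#'
#' @param rr an `rr_series` tibble (the epoch's context window).
#' @return named numeric vector with `Tachy` and `Brady` in \{0, 1\}.
#' @export
rate_flags <- function(rr) {
  x <- rr$rr_ms[rr$valid]
  if (!length(x)) return(c(Tachy = NA_real_, Brady = NA_real_))
  hr <- 60000 / mean(x)
  c(Tachy = as.numeric(hr > 100), Brady = as.numeric(hr < 60))
}

#' Elapsed-time features
#'
#' Hours since the first scored epoch and hours until the last scored
#' epoch. Sleep technicians start scoring near lights-off, so elapsed time
#' carries real information about sleep-cycle position.
#'
#' @param epoch_index 0-based epoch index (vectorised).
#' @param n_epochs total scored epochs.
#' @return tibble with `HoursRec` and `HoursRecEnd`.
#' @export
elapsed_time_features <- function(epoch_index, n_epochs) {
  if (any(epoch_index < 0 | epoch_index >= n_epochs))
    stop("epoch_index out of range")
  tibble::tibble(HoursRec = epoch_index * 30 / 3600,
                 HoursRecEnd = (n_epochs - 1 - epoch_index) * 30 / 3600)
}

# --- moving-average smoothing (NA-aware, shrinking edges) -------------------

smooth_columns <- function(m, k = 5L) {
  n <- nrow(m)
  if (n == 0 || k <= 1) return(m)
  hw <- k %/% 2L
  a <- m; a[is.na(a)] <- 0
  w <- 1 - is.na(m)
  csa <- rbind(0, apply(a, 2, cumsum))
  csw <- rbind(0, apply(w, 2, cumsum))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  sums <- csa[hi + 1L, , drop = FALSE] - csa[lo, , drop = FALSE]
  cnts <- csw[hi + 1L, , drop = FALSE] - csw[lo, , drop = FALSE]
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

# --- per-epoch ECG feature matrix ------------------------------------------

#' Per-epoch ECG feature matrix
#'
#' Runs Pan-Tompkins detection once over the night, then computes the full
#' HRV feature bank for every 30-s epoch from the RR intervals of a centred
#' five-minute context window (clamped at the record ends), plus waveform
#' shape features from the epoch's own samples and elapsed-time features.
#' Every feature column is finally smoothed with a centred 150-s (5-epoch)
#' moving average with shrinking windows at the edges, the convention for
#' sliding HRV staging features.
#'
#' @param trace filtered ECG [signal_trace()] at 200 Hz.
#' @param hyp a [hypnogram()].
#' @param smooth apply the 5-epoch moving average (`TRUE` for staging;
#'   subject-level RBD metrics use the unsmoothed rows).
#' @param context_s HRV context window, seconds.
#' @return tibble with `epoch`, `stage` and one column per manifest feature;
#'   attribute `"manifest"` carries the feature names.
#' @export
ecg_epoch_matrix <- function(trace, hyp, smooth = TRUE, context_s = 300) {
  stopifnot(inherits(trace, "psg_trace"), inherits(hyp, "hypnogram"))
  sl <- epoch_slices(trace, hyp)
  n_ep <- nrow(sl)
  feats <- ecg_feature_manifest()
  if (n_ep == 0) {
    out <- tibble::tibble(epoch = integer(), stage = character())
    out[feats] <- numeric(0)
    return(out)
  }
  peaks <- pan_tompkins(trace)
  rr <- rr_from_peaks(peaks)
  onset <- rr$onset_s; rrv <- rr$rr_ms; val <- rr$valid
  fs <- trace$rate_hz
  t_end <- length(trace$samples) / fs

  # whole-night 4 Hz tachogram, sliced per epoch for the spectral features
  tach <- tachogram_4hz(onset, rrv, val, from = 0, to = t_end)

  half <- context_s / 2
  m <- matrix(NA_real_, n_ep, length(feats), dimnames = list(NULL, feats))
  for (i in seq_len(n_ep)) {
    mid <- hyp$start_offset_s + (sl$epoch[i] + 0.5) * 30
    lo <- max(0, mid - half); hi <- min(t_end, mid + half)
    a <- findInterval(lo, onset) + 1L
    b <- findInterval(hi, onset)
    if (b >= a) {
      idx <- a:b
      rw <- rrv[idx]; vw <- val[idx]
      m[i, TD_NAMES] <- td_hrv_vec(rw, vw)
      if (sum(rw[vw]) / 1000 >= 60 && !is.null(tach)) {
        ta <- max(1L, ceiling((lo - tach$t[1]) * 4) + 1L)
        tb <- min(length(tach$y), floor((hi - tach$t[1]) * 4))
        if (tb - ta + 1L >= 64) m[i, FD_NAMES] <- fd_from_tach(tach$y[ta:tb])
      }
      m[i, NL_NAMES] <- nl_hrv_vec(rw, vw)
      m[i, REG_NAMES] <- reg_vec(rw, vw)
      xv <- rw[vw]
      if (length(xv)) {
        hr <- 60000 / mean(xv)
        m[i, "Tachy"] <- as.numeric(hr > 100)
        m[i, "Brady"] <- as.numeric(hr < 60)
      }
    }
    m[i, SHAPE_NAMES] <-
      shape_vec(trace$samples[(sl$from[i] + 1L):sl$to[i]], fs)
  }
  et <- elapsed_time_features(sl$epoch, n_ep)
  m[, "HoursRec"] <- et$HoursRec
  m[, "HoursRecEnd"] <- et$HoursRecEnd

  if (smooth) m <- smooth_columns(m, 5L)
  out <- tibble::tibble(epoch = sl$epoch, stage = sl$stage)
  out <- dplyr::bind_cols(out, tibble::as_tibble(m))
  attr(out, "manifest") <- feats
  attr(out, "smoothed") <- smooth
  out
}
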