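# Per-epoch EOG and EMG staging features. Epochs are laid out as columns of
# a samples-by-epochs matrix so that spectra, moments and order statistics
# vectorise across the whole night.

EOG_FEATURES <- c("PermEn", "MaxPeak", "Coastline",
                  paste0("BP_", c("0.3_2", "2_4", "4_8", "8_13", "13_30")),
                  paste0("relBP_", c("0.3_2", "2_4", "4_8", "8_13", "13_30")),
                  paste0("P", c(5, 25, 50, 75, 95)),
                  "Skewness", "Kurtosis", "ZCR", "EnergyRatio", "SEF95",
                  "HjorthMobility", "HjorthComplexity")

EMG_FEATURES <- c("Quantile75", "SpectralEntropy", "RelPower",
                  "MotorActivity", "RMS", "Variance", "Coastline",
                  "P50", "P90", "P95", "ZCR",
                  "BP_10_20", "BP_20_40", "BP_40_95",
                  "HjorthActivity", "HjorthMobility", "BurstDuration")

#' Feature manifests for the surface (EOG/EMG) channels
#'
#' @param modality `"EOG"` or `"EMG"`.
#' @return character vector of per-epoch feature names (25 for EOG, 17 for
#'   EMG).
#' @export
surface_feature_manifest <- function(modality = c("EOG", "EMG")) {
  switch(match.arg(modality), EOG = EOG_FEATURES, EMG = EMG_FEATURES)
}

epoch_matrix_of <- function(trace, hyp) {
  sl <- epoch_slices(trace, hyp)
  spe <- round(30 * trace$rate_hz)
  if (nrow(sl) == 0) return(list(m = matrix(numeric(), spe, 0), slices = sl))
  idx <- as.vector(vapply(seq_len(nrow(sl)),
                          function(i) (sl$from[i] + 1L):sl$to[i],
                          integer(spe)))
  list(m = matrix(trace$samples[idx], nrow = spe), slices = sl)
}

# one-sided power spectrum per column (epoch); freq resolution fs/nrow
epoch_spectra <- function(m, fs) {
  n <- nrow(m)
  xm <- sweep(m, 2, colMeans(m))
  sp <- Mod(stats::mvfft(xm))^2 / (n * fs)
  half <- n %/% 2L
  list(freq = (seq_len(half) - 1) * fs / n, psd = 2 * sp[seq_len(half), , drop = FALSE])
}

spec_band <- function(sp, lo, hi) {
  sel <- sp$freq >= lo & sp$freq < hi
  colSums(sp$psd[sel, , drop = FALSE]) * (sp$freq[2] - sp$freq[1])
}

col_quantiles <- function(m, probs) {
  srt <- apply(m, 2, sort)
  n <- nrow(m)
  # type-7 quantiles from the sorted columns
  out <- vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo, ] + (h - lo) * (srt[hi, ] - srt[lo, ])
  }, numeric(ncol(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out  # epochs x probs
}

# normalised permutation entropy, order 3, delay 1, per column
col_perm_entropy <- function(m) {
  n <- nrow(m)
  a <- m[1:(n - 2), , drop = FALSE]
  b <- m[2:(n - 1), , drop = FALSE]
  cc <- m[3:n, , drop = FALSE]
  code <- (a < b) + 2L * (b < cc) + 4L * (a < cc)
  apply(code, 2, function(v) {
    p <- tabulate(v + 1L, nbins = 8L)
    p <- p[p > 0] / length(v)
    h <- -sum(p * log(p))
    h / log(6)
  })
}

col_zcr <- function(m) {
  s <- sign(m)
  colSums(s[-nrow(m), , drop = FALSE] * s[-1, , drop = FALSE] < 0) /
    (nrow(m) - 1)
}

hjorth_cols <- function(m) {
  v0 <- apply(m, 2, stats::var)
  d1 <- diff(m)
  v1 <- apply(d1, 2, stats::var)
  d2 <- diff(d1)
  v2 <- apply(d2, 2, stats::var)
  mob <- sqrt(v1 / v0)
  cpx <- sqrt(v2 / v1) / mob
  list(activity = v0, mobility = mob, complexity = cpx)
}

#' Per-epoch EOG staging features
#'
#' Twenty-five features per 30-s epoch targeting rapid-eye-movement
#' phenomenology: normalised permutation entropy (order 3, delay 1), maximum
#' absolute peak amplitude and coastline (sum of absolute successive
#' differences) — the features most diagnostic of REM — plus absolute and
#' relative band powers (0.3-2, 2-4, 4-8, 8-13, 13-30 Hz), amplitude
#' percentiles (5/25/50/75/95), skewness, kurtosis, zero-crossing rate, the
#' first/second half energy ratio, 95% spectral edge frequency, and Hjorth
#' mobility and complexity.
#'
#' @param trace filtered EOG [signal_trace()] at 200 Hz.
#' @param hyp a [hypnogram()].
#' @return tibble with `epoch`, `stage` and the 25 feature columns.
#' @export
eog_epoch_features <- function(trace, hyp) {
  stopifnot(trace$modality == "EOG")
  em <- epoch_matrix_of(trace, hyp)
  m <- em$m; sl <- em$slices
  out <- tibble::tibble(epoch = sl$epoch, stage = sl$stage)
  if (nrow(sl) == 0) { out[EOG_FEATURES] <- numeric(0); return(out) }
  fs <- trace$rate_hz
  sp <- epoch_spectra(m, fs)
  bands <- rbind(c(0.3, 2), c(2, 4), c(4, 8), c(8, 13), c(13, 30))
  bp <- vapply(seq_len(nrow(bands)),
               function(i) spec_band(sp, bands[i, 1], bands[i, 2]),
               numeric(ncol(m)))
  if (is.null(dim(bp))) bp <- matrix(bp, nrow = 1)
  tot <- spec_band(sp, 0.3, 30)
  rel <- bp / ifelse(tot > 0, tot, NA_real_)
  qs <- col_quantiles(m, c(.05, .25, .50, .75, .95))
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  sdv <- sqrt(colMeans(ctr^2))
  skew <- colMeans(ctr^3) / ifelse(sdv > 0, sdv^3, NA_real_)
  kurt <- colMeans(ctr^4) / ifelse(sdv > 0, sdv^4, NA_real_)
  n <- nrow(m)
  e1 <- colSums(m[seq_len(n %/% 2), , drop = FALSE]^2)
  e2 <- colSums(m[(n %/% 2 + 1):n, , drop = FALSE]^2)
  hj <- hjorth_cols(m)
  # 95% spectral edge within 0.3-30 Hz
  sel <- which(sp$freq >= 0.3 & sp$freq < 30)
  cum <- apply(sp$psd[sel, , drop = FALSE], 2, cumsum)
  sef <- vapply(seq_len(ncol(m)), function(j) {
    tt <- cum[nrow(cum), j]
    if (tt <= 0) return(NA_real_)
    sp$freq[sel[which(cum[, j] >= 0.95 * tt)[1]]]
  }, numeric(1))

  vals <- cbind(col_perm_entropy(m),
                apply(abs(m), 2, max),
                colSums(abs(diff(m))),
                bp, rel, qs, skew, kurt, col_zcr(m),
                e1 / ifelse(e2 > 0, e2, NA_real_), sef,
                hj$mobility, hj$complexity)
  colnames(vals) <- EOG_FEATURES
  dplyr::bind_cols(out, tibble::as_tibble(vals))
}

#' Per-epoch EMG staging features
#'
#' Seventeen features per 30-s epoch quantifying submental muscle tone: the
#' 75th percentile of the rectified amplitude, spectral entropy, relative
#' power (epoch 10-95 Hz power over the whole-night median), motor activity
#' (fraction of 1-s mini-epochs whose RMS exceeds twice the night's
#' 5th-percentile RMS — a robust noise floor), RMS, variance, coastline,
#' rectified-amplitude percentiles (50/90/95), zero-crossing rate, band
#' powers 10-20/20-40/40-95 Hz, Hjorth activity and mobility, and the mean
#' duration of supra-threshold bursts in seconds.
#'
#' @param trace filtered EMG [signal_trace()] at 200 Hz.
#' @param hyp a [hypnogram()].
#' @return tibble with `epoch`, `stage` and the 17 feature columns.
#' @export
emg_epoch_features <- function(trace, hyp) {
  stopifnot(trace$modality == "EMG")
  em <- epoch_matrix_of(trace, hyp)
  m <- em$m; sl <- em$slices
  out <- tibble::tibble(epoch = sl$epoch, stage = sl$stage)
  if (nrow(sl) == 0) { out[EMG_FEATURES] <- numeric(0); return(out) }
  fs <- trace$rate_hz
  sp <- epoch_spectra(m, fs)
  p_tot <- spec_band(sp, 10, 95)
  night_med <- stats::median(p_tot)
  rel_power <- if (night_med > 0) p_tot / night_med else rep(NA_real_, ncol(m))

  # spectral entropy over the 10-95 Hz band, normalised to [0, 1]
  sel <- which(sp$freq >= 10 & sp$freq < 95)
  pm <- sp$psd[sel, , drop = FALSE]
  cs <- colSums(pm)
  spec_ent <- vapply(seq_len(ncol(m)), function(j) {
    if (cs[j] <= 0) return(NA_real_)
    p <- pm[, j] / cs[j]
    p <- p[p > 0]
    -sum(p * log(p)) / log(length(sel))
  }, numeric(1))

  # 1-s mini-epoch RMS grid: 30 mini-epochs per epoch
  spe <- nrow(m)
  sec <- round(fs)
  rms_sec <- sqrt(colMeans(matrix(m^2, nrow = sec)))  # (30 * n_epochs)
  rms_mat <- matrix(rms_sec, nrow = spe %/% sec)
  floor_rms <- stats::quantile(rms_sec, 0.05, names = FALSE)
  thr <- 2 * floor_rms
  supra <- rms_mat > thr
  motor <- colMeans(supra)
  burst_dur <- vapply(seq_len(ncol(supra)), function(j) {
    r <- rle(supra[, j])
    if (!any(r$values)) return(0)
    mean(r$lengths[r$values])
  }, numeric(1))

  am <- abs(m)
  qs <- col_quantiles(am, c(.50, .75, .90, .95))
  hj <- hjorth_cols(m)
  bp <- cbind(spec_band(sp, 10, 20), spec_band(sp, 20, 40), spec_band(sp, 40, 95))

  vals <- cbind(qs[, 2], spec_ent, rel_power, motor,
                sqrt(colMeans(m^2)), apply(m, 2, stats::var),
                colSums(abs(diff(m))),
                qs[, 1], qs[, 3], qs[, 4], col_zcr(m),
                bp, hj$activity, hj$mobility, burst_dur)
  colnames(vals) <- EMG_FEATURES
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  # per-epoch spectral exponent over 10-95 Hz, reused by the RBD metrics
  lf <- log(sp$freq[sel])
  wts <- (lf - mean(lf)) / sum((lf - mean(lf))^2)
  attr(out, "beta") <- as.numeric(wts %*% log(pmax(pm, 1e-300)))
  out
}
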