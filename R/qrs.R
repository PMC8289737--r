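#' Pan-Tompkins QRS detection
#'
#' The canonical detector implemented in full: five-point derivative,
#' squaring, 150-ms moving-window integration, adaptive dual thresholds with
#' running signal/noise peak estimates, a 200-ms refractory period, T-wave
#' rejection by slope comparison for candidate beats arriving within 360 ms,
#' and a search-back pass at half threshold when more than 1.66 times the
#' running RR average elapses without a detection. Detections are finally
#' localised to the largest absolute excursion of the band-passed ECG within
#' +/-40 ms.
#'
#' @param trace a filtered ECG [signal_trace()] (see [filter_ecg()]).
#' @return a tibble of class `rpeak_series` with columns `time_s` and
#'   `quality` (`"valid"` for threshold detections, `"suspect"` for
#'   search-back rescues).
#' @export
pan_tompkins <- function(trace) {
  stopifnot(inherits(trace, "psg_trace"))
  if (trace$modality != "ECG") stop("pan_tompkins expects an ECG trace")
  fs <- trace$rate_hz
  x <- trace$samples
  if (length(x) < 10 * fs) stop("trace shorter than 10 s: thresholds cannot adapt")

  # derivative (centred five-point), squaring, moving-window integration
  dk <- c(1, 2, 0, -2, -1) * fs / 8
  deriv <- stats::filter(x, dk, method = "convolution", sides = 2)
  deriv[is.na(deriv)] <- 0
  sq <- as.numeric(deriv)^2
  w <- round(0.150 * fs)
  hwv <- w %/% 2L
  cs <- cumsum(sq)
  n <- length(sq)
  lo <- pmax(seq_len(n) - hwv, 1L); hi <- pmin(seq_len(n) + hwv, n)
  mwi <- (cs[hi] - cs[lo] + sq[lo]) / (hi - lo + 1L)

  # candidate fiducial points: local maxima of the integrated signal.
  # Maxima under 1% of the upper-decile peak level are baseline ripple and
  # are dropped before the sequential threshold pass.
  is_pk <- c(FALSE, mwi[2:(n - 1)] >= mwi[1:(n - 2)] &
                    mwi[2:(n - 1)] > mwi[3:n], FALSE)
  cand <- which(is_pk)
  if (length(cand) > 10)
    cand <- cand[mwi[cand] > 0.01 * stats::quantile(mwi[cand], 0.9, names = FALSE)]
  if (length(cand) == 0)
    return(structure(tibble::tibble(time_s = numeric(), quality = character()),
                     class = c("rpeak_series", "tbl_df", "tbl", "data.frame")))

  # threshold initialisation from the first two seconds
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  refr <- round(0.200 * fs)
  twin <- round(0.360 * fs)
  peaks <- integer(length(cand))
  suspect <- logical(length(cand))
  np <- 0L
  rr_buf <- numeric(8)
  nrr <- 0L
  last <- -Inf
  slope_at <- function(i) {
    lo <- max(1, i - round(0.075 * fs)); hi <- min(n, i + round(0.075 * fs))
    max(abs(sq[lo:hi]))
  }
  last_slope <- 0
  push_rr <- function(v) {
    nrr <<- nrr + 1L
    rr_buf[((nrr - 1L) %% 8L) + 1L] <<- v
  }
  rr_avg <- function() sum(rr_buf[seq_len(min(nrr, 8L))]) / min(nrr, 8L)
  i_cand <- 1L
  n_cand <- length(cand)
  while (i_cand <= n_cand) {
    i <- cand[i_cand]
    v <- mwi[i]
    accept <- FALSE
    if (v > thr1 && (i - last) > refr) {
      accept <- TRUE
      if (np > 0L && (i - last) < twin) {
        # possible T wave: reject if upstroke slope under half the previous
        if (slope_at(i) < 0.5 * last_slope) accept <- FALSE
      }
    }
    if (accept) {
      if (np > 0L) push_rr(i - last)
      last_slope <- slope_at(i)
      np <- np + 1L
      peaks[np] <- i
      last <- i
      spki <- 0.125 * v + 0.875 * spki
    } else if (v > thr1 && (i - last) <= refr) {
      # inside the refractory period: keep whichever candidate carries the
      # larger integrated energy (a noise blip must not mask the QRS)
      if (np > 0L && v > mwi[peaks[np]]) {
        peaks[np] <- i
        last <- i
        last_slope <- slope_at(i)
        spki <- 0.125 * v + 0.875 * spki
        if (nrr >= 1L && np >= 2L)
          rr_buf[((nrr - 1L) %% 8L) + 1L] <- i - peaks[np - 1L]
      }
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)

    # search-back: missed beat if the gap exceeds 1.66 * running RR average
    if (nrr >= 2L && i_cand < n_cand) {
      nxt <- cand[i_cand + 1L]
      if ((nxt - last) > 1.66 * rr_avg()) {
        sel <- cand > last + refr & cand < nxt
        if (any(sel)) {
          segc <- cand[sel]
          j <- segc[which.max(mwi[segc])]
          if (mwi[j] > 0.5 * thr1 && (j - last) > refr) {
            push_rr(j - last)
            np <- np + 1L
            peaks[np] <- j
            suspect[np] <- TRUE
            last <- j
            last_slope <- slope_at(j)
            spki <- 0.25 * mwi[j] + 0.75 * spki
            thr1 <- npki + 0.25 * (spki - npki)
          }
        }
      }
    }
    i_cand <- i_cand + 1L
  }
  peaks <- peaks[seq_len(np)]
  quality <- ifelse(suspect[seq_len(np)], "suspect", "valid")
  ord <- order(peaks)
  peaks <- peaks[ord]; quality <- quality[ord]

  # localise on the band-passed signal within +/-40 ms, polarity-corrected
  # so that template side lobes of the opposite sign are not picked
  pol <- if (abs(max(x)) >= abs(min(x))) 1 else -1
  hw <- round(0.040 * fs)
  loc <- vapply(peaks, function(i) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    lo + which.max(pol * x[lo:hi]) - 1L
  }, numeric(1))
  keep <- !duplicated(loc)
  structure(tibble::tibble(time_s = (loc[keep] - 1) / fs, quality = quality[keep]),
            class = c("rpeak_series", "tbl_df", "tbl", "data.frame"))
}

#' RR interval series from detected R peaks
#'
#' Successive inter-beat intervals in milliseconds with a physiological
#' validity screen: intervals outside 300-2000 ms, or deviating more than
#' 20% from an 11-beat running median, are flagged invalid. Flagged
#' intervals are excluded from every downstream statistic but are never
#' interpolated.
#'
#' @param peaks an `rpeak_series` from [pan_tompkins()].
#' @return a tibble of class `rr_series` with columns `onset_s` (time of the
#'   interval's opening beat), `rr_ms` and `valid`.
#' @export
rr_from_peaks <- function(peaks) {
  t <- peaks$time_s
  if (length(t) < 2)
    return(structure(tibble::tibble(onset_s = numeric(), rr_ms = numeric(),
                                    valid = logical()),
                     class = c("rr_series", "tbl_df", "tbl", "data.frame")))
  rr <- diff(t) * 1000
  onset <- t[-length(t)]
  valid <- rr >= 300 & rr <= 2000
  if (length(rr) >= 3) {
    k <- min(11L, length(rr) - (1 - length(rr) %% 2))  # largest odd <= len
    med <- stats::runmed(rr, k, endrule = "median")
    valid <- valid & abs(rr - med) <= 0.2 * med
  }
  structure(tibble::tibble(onset_s = onset, rr_ms = rr, valid = valid),
            class = c("rr_series", "tbl_df", "tbl", "data.frame"))
}
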