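# Shared fixtures, built in code and memoised for the duration of the run.

the_fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(the_fixture_env[[key]]))
    the_fixture_env[[key]] <- force(expr)
  the_fixture_env[[key]]
}

# a short two-cohort cohort with 1-h nights: enough sleep architecture for
# staging/detection mechanics without overnight cost
tiny_cohort <- function() {
  memo("tiny_cohort", {
    cfg <- synth_config(n_hc = 4, n_rbd = 4, night_epochs = 120, seed = 11)
    suppressWarnings(synth_cohort_features(cfg))
  })
}

tiny_metrics <- function() {
  memo("tiny_metrics", cohort_subject_metrics(tiny_cohort()$caches))
}

sine_trace <- function(freq_hz, dur_s = 30, fs = 200, amp = 1,
                       modality = "ECG") {
  t <- seq(1 / fs, dur_s, by = 1 / fs)
  signal_trace(amp * sin(2 * pi * freq_hz * t), fs, modality)
}

# single-stage config: an identity transition matrix freezes the chain in W
constant_stage_cfg <- function(hr = 60, night_epochs = 4, sdnn = 2,
                               noise_snr_db = 100, seed = 1) {
  synth_config(n_hc = 1, n_rbd = 0, night_epochs = night_epochs,
               transition = diag(3),
               hr_by_stage = c(W = hr, NREM = hr, REM = hr),
               sdnn_by_stage = c(W = sdnn, NREM = sdnn, REM = sdnn),
               noise_snr_db = noise_snr_db, seed = seed)
}

make_rr <- function(rr_ms, valid = rep(TRUE, length(rr_ms)),
                    onset_s = cumsum(c(0, rr_ms[-length(rr_ms)])) / 1000) {
  structure(tibble::tibble(onset_s = onset_s, rr_ms = rr_ms, valid = valid),
            class = c("rr_series", "tbl_df", "tbl", "data.frame"))
}

# independent brute-force oracle for the time-domain HRV features
oracle_td <- function(rr) {
  n <- length(rr)
  d <- rr[-1] - rr[-n]
  nn50 <- sum(abs(d) > 50)
  list(meanRR = sum(rr) / n,
       medianRR = stats::median(rr),
       SDNN = sqrt(sum((rr - sum(rr) / n)^2) / (n - 1)),
       RMSSD = sqrt(sum(d^2) / length(d)),
       SDSD = sqrt(sum((d - sum(d) / length(d))^2) / (length(d) - 1)),
       NN50 = nn50,
       pNN50 = nn50 / length(d))
}

# independent LZ76 phrase-count oracle: string-search formulation — each new
# phrase is the shortest extension whose body (all but its last symbol) is
# not reproducible as a substring of everything before that last symbol
oracle_lz76 <- function(s) {
  str <- paste(s, collapse = "")
  n <- nchar(str)
  if (n == 0) return(0L)
  phrases <- 0L
  i <- 1L
  while (i <= n) {
    len <- 1L
    while (i + len <= n &&
           grepl(substr(str, i, i + len - 1L),
                 substr(str, 1L, i + len - 2L), fixed = TRUE)) {
      len <- len + 1L
    }
    phrases <- phrases + 1L
    i <- i + len
  }
  phrases
}
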