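# Synthetic overnight PSG cohorts with ground truth. The generator encodes
# the statistical structure the pipeline assumes: a Markov three-state
# hypnogram, an RR tachogram with stage-dependent mean, variability and
# LF/HF balance, REM-locked eye-movement deflections in the EOG, and
# stage-dependent submental tone where the RBD condition re-introduces
# intermittent REM tone (simulated RSWA) and attenuates the REM/NREM HRV
# contrast.

#' Synthetic cohort configuration
#'
#' Defaults describe the study conditions used throughout the test-suite:
#' 8-h nights (960 epochs), stage-dependent heart rate (W 70, NREM 60,
#' REM 66 bpm), SDNN (W 55, NREM 45, REM 50 ms) and LF/HF balance (W 3,
#' NREM 1, REM 3.5 — sympathetic REM, parasympathetic NREM), 4 REM
#' eye-movement events per minute, submental tone of 12/5/1 uV RMS in
#' W/NREM/REM, and an RSWA effect of 0.8 for RBD subjects.
#'
#' @param n_hc,n_rbd cohort sizes.
#' @param night_epochs epochs per night (960 = 8 h).
#' @param transition 3x3 row-stochastic stage transition matrix (W, NREM,
#'   REM order); the default has stationary distribution (0.2, 0.6, 0.2).
#' @param hr_by_stage mean heart rate per stage, bpm.
#' @param sdnn_by_stage target RR standard deviation per stage, ms.
#' @param lfhf_by_stage LF/HF spectral power ratio per stage.
#' @param rem_eog_event_rate rapid-eye-movement deflections per minute of
#'   REM.
#' @param emg_tone_by_stage submental tone per stage, uV RMS; the REM entry
#'   is the atonic floor.
#' @param rswa_effect REM-sleep-without-atonia effect size in \[0, 1\] for
#'   RBD subjects: scales the duty cycle and level of intermittent REM tone
#'   and the shrinkage of the REM/NREM HRV contrast.
#' @param couple_hrv also attenuate the HRV contrast for RBD subjects
#'   (`FALSE` decouples the two mechanisms for ablation).
#' @param noise_snr_db additive ECG noise level.
#' @param rate_hz sampling rate of all generated signals.
#' @param seed base seed; per-subject streams are derived from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_hc = 20, n_rbd = 20, night_epochs = 960,
                         transition = rbind(c(0.90, 0.10, 0.00),
                                            c(1/30, 28/30, 1/30),
                                            c(0.00, 0.10, 0.90)),
                         hr_by_stage = c(W = 70, NREM = 60, REM = 66),
                         sdnn_by_stage = c(W = 55, NREM = 45, REM = 50),
                         lfhf_by_stage = c(W = 3, NREM = 1, REM = 3.5),
                         rem_eog_event_rate = 4,
                         emg_tone_by_stage = c(W = 12, NREM = 5, REM = 1),
                         rswa_effect = 0.8, couple_hrv = TRUE,
                         noise_snr_db = 15, rate_hz = 200, seed = 1) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(3, 3)) ||
      any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0))
    stop("transition must be a 3x3 row-stochastic matrix")
  stopifnot(rswa_effect >= 0, rswa_effect <= 1,
            all(hr_by_stage > 0), all(emg_tone_by_stage > 0))
  structure(list(n_hc = n_hc, n_rbd = n_rbd, night_epochs = night_epochs,
                 transition = transition, hr_by_stage = hr_by_stage,
                 sdnn_by_stage = sdnn_by_stage, lfhf_by_stage = lfhf_by_stage,
                 rem_eog_event_rate = rem_eog_event_rate,
                 emg_tone_by_stage = emg_tone_by_stage,
                 rswa_effect = rswa_effect, couple_hrv = couple_hrv,
                 noise_snr_db = noise_snr_db, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "synth_config")
}

derive_seed <- function(seed, i, k = 0) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + k * 131) %% 2147483629)
}

#' Generate a Markov hypnogram
#'
#' @param cfg a [synth_config()].
#' @param seed stream seed (defaults to the config seed).
#' @return a [hypnogram()] of `night_epochs` epochs, started in W.
#' @export
generate_hypnogram <- function(cfg = synth_config(), seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$night_epochs
  st <- integer(n)
  st[1] <- 1L
  u <- stats::runif(n)
  cum <- t(apply(cfg$transition, 1, cumsum))
  for (i in seq_len(n - 1L))
    st[i + 1L] <- findInterval(u[i], cum[st[i], ], left.open = TRUE) + 1L
  hypnogram(STAGES3[st])
}

# stage-dependent RR parameters, with the REM/NREM contrast shrunk toward
# NREM by `shrink` (the HRV half of the RSWA effect)
rr_stage_params <- function(cfg, shrink = 0) {
  hr <- cfg$hr_by_stage; sdnn <- cfg$sdnn_by_stage; lfhf <- cfg$lfhf_by_stage
  if (shrink > 0) {
    hr["REM"] <- hr["NREM"] + (1 - shrink) * (hr["REM"] - hr["NREM"])
    sdnn["REM"] <- sdnn["NREM"] + (1 - shrink) * (sdnn["REM"] - sdnn["NREM"])
    lfhf["REM"] <- lfhf["NREM"] + (1 - shrink) * (lfhf["REM"] - lfhf["NREM"])
  }
  list(mean_rr = 60000 / hr, sdnn = sdnn, lfhf = lfhf)
}

#' Generate a synthetic ECG trace
#'
#' The RR series is drawn beat by beat as the stage mean plus sinusoidal
#' LF (0.1 Hz) and HF (0.25 Hz) modulation whose amplitude ratio matches
#' the stage's LF/HF target, plus white jitter sized to hit the stage SDNN.
#' The waveform convolves a QRS-like template (Mexican-hat, ~25 ms) with
#' the beat train, and adds baseline drift and white noise at
#' `noise_snr_db`.
#'
#' @param hyp a [hypnogram()].
#' @param cfg a [synth_config()].
#' @param seed stream seed.
#' @param rswa_effect HRV-contrast attenuation for this subject (0 for HC).
#' @return list with `trace` (ECG [signal_trace()]) and `peaks_s` (ground
#'   truth R-peak times).
#' @export
generate_ecg <- function(hyp, cfg = synth_config(), seed = cfg$seed,
                         rswa_effect = 0) {
  set.seed(seed)
  fs <- cfg$rate_hz
  T_s <- length(hyp$stages) * 30
  pars <- rr_stage_params(cfg, if (cfg$couple_hrv) rswa_effect else 0)
  stages <- as.integer(hyp$stages)
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  # resting heart rate and sympathovagal balance vary between subjects and
  # drift slowly within the night: a per-subject rate scale (so absolute
  # rate does not identify the stage across subjects), a per-bout mean-RR
  # offset, and a per-subject LF/HF scale. Stage SDNN targets stay exact.
  subj_rr <- exp(stats::rnorm(1, 0, 0.10))
  subj_lfhf <- exp(stats::rnorm(1, 0, 0.30))
  ep_bout <- cumsum(c(1L, diff(stages) != 0L))
  bout_rr <- stats::rnorm(max(ep_bout), 0, 25)
  tt <- numeric(ceiling(T_s / 0.3))
  k <- 0L; t <- 0
  jit <- stats::rnorm(length(tt))
  while (t < T_s) {
    ep <- min(length(stages), floor(t / 30) + 1L)
    s <- stages[ep]
    sdnn <- pars$sdnn[s]; rho <- pars$lfhf[s] * subj_lfhf
    a_lf <- sqrt(2 * 0.91 * sdnn^2 * rho / (1 + rho))
    a_hf <- sqrt(2 * 0.91 * sdnn^2 / (1 + rho))
    rr <- pars$mean_rr[s] * subj_rr + bout_rr[ep_bout[ep]] +
      a_lf * sin(2 * pi * 0.1 * t + ph1) +
      a_hf * sin(2 * pi * 0.25 * t + ph2) +
      0.3 * sdnn * jit[k + 1L]
    rr <- max(rr, 320)
    k <- k + 1L
    tt[k] <- t
    t <- t + rr / 1000
  }
  peaks <- tt[seq_len(k)][-1]    # drop the t=0 boundary beat
  n <- T_s * fs
  delta <- numeric(n)
  delta[pmin(n, round(peaks * fs) + 1L)] <- 1
  # Mexican-hat QRS template, ~25 ms characteristic width, 1 mV peak
  tw <- seq(-0.06, 0.06, by = 1 / fs)
  sg <- 0.012
  tpl <- (1 - (tw / sg)^2) * exp(-tw^2 / (2 * sg^2)) * 1000
  x <- os_convolve(delta, tpl)
  x <- x + 150 * sin(2 * pi * 0.2 * seq_len(n) / fs)
  snr_sd <- sqrt(mean(x^2)) / 10^(cfg$noise_snr_db / 20)
  x <- x + stats::rnorm(n, sd = snr_sd)
  list(trace = signal_trace(x, fs, "ECG"), peaks_s = peaks)
}

# coloured band-limited noise: white noise convolved with a linear-phase
# kernel whose magnitude follows the requested band and spectral slope
# (kernel designed once per shape by frequency sampling and cached)
shaped_noise <- function(n, fs, f_lo, f_hi, slope = 0) {
  key <- sprintf("noise_%g_%g_%g_%g", fs, f_lo, f_hi, slope)
  k <- the_filter_cache[[key]]
  if (is.null(k)) {
    m <- 1024L
    f <- seq(0, floor(m / 2)) * fs / m
    h <- numeric(length(f))
    inb <- f >= f_lo & f <= f_hi
    h[inb] <- (pmax(f[inb], f_lo) / ((f_lo + f_hi) / 2))^(slope / 2)
    ramp_lo <- f > f_lo * 0.7 & f < f_lo
    h[ramp_lo] <- 0.5 * (1 - cos(pi * (f[ramp_lo] - f_lo * 0.7) / (f_lo * 0.3))) *
      (f_lo / ((f_lo + f_hi) / 2))^(slope / 2)
    full <- c(h, rev(h[-c(1, length(h))]))[seq_len(m)]
    k0 <- Re(stats::fft(full, inverse = TRUE)) / m
    k <- c(k0[(m / 2 + 2):m], k0[seq_len(m / 2 + 1)])  # centre the kernel
    k <- k * 0.5 * (1 - cos(2 * pi * seq_along(k) / (length(k) + 1)))
    the_filter_cache[[key]] <- k
  }
  y <- os_convolve(stats::rnorm(n), k)
  y / sqrt(mean(y^2))
}

#' Generate a synthetic EOG trace
#'
#' Band-limited background activity plus sawtooth-like conjugate
#' eye-movement deflections (0.4 s, 100-300 uV) at `rem_eog_event_rate`
#' during REM epochs and slower rolling movements at a reduced rate during
#' wake.
#'
#' @param hyp a [hypnogram()].
#' @param cfg a [synth_config()].
#' @param seed stream seed.
#' @return an EOG [signal_trace()].
#' @export
generate_eog <- function(hyp, cfg = synth_config(), seed = cfg$seed) {
  set.seed(seed)
  fs <- cfg$rate_hz
  stages <- as.character(hyp$stages)
  n <- length(stages) * 30 * fs
  x <- 15 * shaped_noise(n, fs, 0.3, 8, slope = -1)
  ev_shape <- function(len, rise_frac) {
    nr <- max(2L, round(len * rise_frac))
    c(seq(0, 1, length.out = nr), seq(1, 0, length.out = len - nr))[seq_len(len)]
  }
  # collect event parameters first, then add them in place
  ev_t0 <- numeric(0); ev_dur <- numeric(0); ev_amp <- numeric(0)
  ev_rise <- numeric(0)
  for (e in seq_along(stages)) {
    t_ep <- (e - 1) * 30
    if (stages[e] == "REM") {
      k <- stats::rpois(1, cfg$rem_eog_event_rate / 2)
      if (k > 0) {
        ev_t0 <- c(ev_t0, stats::runif(k, t_ep, t_ep + 29.4))
        ev_dur <- c(ev_dur, rep(0.4, k))
        ev_amp <- c(ev_amp, sample(c(-1, 1), k, TRUE) * stats::runif(k, 100, 300))
        ev_rise <- c(ev_rise, rep(0.3, k))
      }
    } else if (stages[e] == "W") {
      k <- stats::rpois(1, 0.5)
      if (k > 0) {
        ev_t0 <- c(ev_t0, stats::runif(k, t_ep, t_ep + 27.5))
        ev_dur <- c(ev_dur, rep(2, k))
        ev_amp <- c(ev_amp, sample(c(-1, 1), k, TRUE) * stats::runif(k, 60, 100))
        ev_rise <- c(ev_rise, rep(0.5, k))
      }
    }
  }
  for (j in seq_along(ev_t0)) {
    i0 <- round(ev_t0[j] * fs) + 1L
    len <- round(ev_dur[j] * fs)
    if (i0 + len > n) next
    idx <- i0:(i0 + len - 1L)
    x[idx] <- x[idx] + ev_amp[j] * ev_shape(len, ev_rise[j])
  }
  signal_trace(x, fs, "EOG")
}

#' Generate a synthetic EMG trace
#'
#' 10-95 Hz coloured noise whose per-second RMS envelope follows the
#' stage-dependent tone. For RBD subjects (`rswa_effect > 0`) REM atonia is
#' interrupted by intermittent tonic segments (mean 20 s, duty cycle
#' `0.6 * rswa_effect`) at a level between the atonic floor and the NREM
#' tone, plus phasic bursts at `8 * rswa_effect` per minute — RSWA is
#' physiologically intermittent, and the atonia index's rolling-minimum
#' noise correction would cancel a uniformly elevated tone.
#'
#' @param hyp a [hypnogram()].
#' @param cfg a [synth_config()].
#' @param seed stream seed.
#' @param rswa_effect RSWA effect size for this subject (0 for HC).
#' @return an EMG [signal_trace()].
#' @export
generate_emg <- function(hyp, cfg = synth_config(), seed = cfg$seed,
                         rswa_effect = 0) {
  set.seed(seed)
  fs <- cfg$rate_hz
  stages <- as.character(hyp$stages)
  n_sec <- length(stages) * 30
  tone <- cfg$emg_tone_by_stage
  sec_stage <- rep(stages, each = 30)
  env <- unname(tone[match(sec_stage, names(tone))])
  # real submental tone is not a per-stage constant: each bout carries a
  # lognormal tone offset and every subject a global scale, so stage tone
  # distributions overlap across (and within) nights instead of being a
  # perfectly separable stage oracle
  subj_scale <- exp(stats::rnorm(1, 0, 0.2))
  bouts <- rle(sec_stage)
  bout_fac <- exp(stats::rnorm(length(bouts$lengths), 0, 0.25))
  bout_env <- rep(bout_fac, bouts$lengths) * subj_scale
  env <- env * bout_env
  if (rswa_effect > 0) {
    rem_sec <- which(sec_stage == "REM")
    tonic_level <- tone["REM"] + rswa_effect * (tone["NREM"] - tone["REM"])
    duty <- 0.6 * rswa_effect
    p_off <- 1 / 20                      # mean tonic segment ~20 s
    p_on <- duty * p_off / max(1 - duty, 1e-6)
    state <- FALSE
    u <- stats::runif(length(rem_sec))
    for (j in seq_along(rem_sec)) {
      state <- if (state) u[j] > p_off else u[j] < p_on
      if (state) env[rem_sec[j]] <- tonic_level * bout_env[rem_sec[j]]
    }
    # phasic bursts: short high-amplitude twitches
    burst_rate <- 8 * rswa_effect / 60
    kb <- stats::rpois(length(rem_sec), burst_rate)
    for (j in which(kb > 0)) {
      len <- max(1L, round(stats::runif(1, 0.5, 2)))
      idx <- rem_sec[j] + seq_len(len) - 1L
      idx <- idx[idx <= n_sec & sec_stage[pmin(idx, n_sec)] == "REM"]
      env[idx] <- 4 * tone["NREM"] * bout_env[idx]
    }
  }
  # broadband measurement floor, proportional to the configured atonic tone
  # so amplitude homogeneity (tone scaling) is preserved exactly
  env <- sqrt(env^2 + (0.5 * tone[["REM"]])^2)
  x <- shaped_noise(n_sec * fs, fs, 10, 95, slope = -1)
  x <- x * rep(env, each = fs)
  signal_trace(x, fs, "EMG")
}

#' Generate one synthetic subject
#'
#' @param cfg a [synth_config()].
#' @param subject_id identifier.
#' @param cohort `"HC"` or `"RBD"` (RBD applies `cfg$rswa_effect`).
#' @param seed stream seed.
#' @return list with `recording` (a [recording()] with hypnogram attached)
#'   and `truth` (R-peak times, per-subject rswa effect).
#' @export
generate_recording <- function(cfg = synth_config(), subject_id = "S01",
                               cohort = c("HC", "RBD"), seed = cfg$seed) {
  cohort <- match.arg(cohort)
  rswa <- if (cohort == "RBD") cfg$rswa_effect else 0
  hyp <- generate_hypnogram(cfg, seed = derive_seed(seed, 1))
  ecg <- generate_ecg(hyp, cfg, seed = derive_seed(seed, 2), rswa_effect = rswa)
  eog <- generate_eog(hyp, cfg, seed = derive_seed(seed, 3))
  emg <- generate_emg(hyp, cfg, seed = derive_seed(seed, 4), rswa_effect = rswa)
  rec <- recording(subject_id, list(ecg$trace, eog, emg),
                   hypnogram = hyp, cohort = cohort)
  list(recording = rec,
       truth = list(peaks_s = ecg$peaks_s, rswa_effect = rswa,
                    hypnogram = hyp))
}

#' Generate a synthetic cohort
#'
#' Subjects are generated with per-subject seeds derived from the config
#' seed, so any subject can be re-materialised independently. With `dir`
#' set, signals are written as EDF, hypnograms as interchange CSV and a
#' JSON manifest is emitted; otherwise the recordings are returned
#' in-memory (mind the footprint for large cohorts — prefer
#' [synth_cohort_features()] for full-scale runs).
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory.
#' @return with `dir`: the manifest tibble (subject_id, cohort, file
#'   paths); otherwise a list of [generate_recording()] results plus the
#'   manifest.
#' @export
generate_cohort <- function(cfg = synth_config(), dir = NULL) {
  ids <- c(sprintf("hc%02d", seq_len(cfg$n_hc)),
           sprintf("rbd%02d", seq_len(cfg$n_rbd)))
  cohorts <- rep(c("HC", "RBD"), c(cfg$n_hc, cfg$n_rbd))
  manifest <- tibble::tibble(subject_id = ids, cohort = cohorts,
                             seed = derive_seed(cfg$seed, seq_along(ids), 9))
  if (is.null(dir)) {
    subs <- lapply(seq_along(ids), function(i)
      generate_recording(cfg, ids[i], cohorts[i], seed = manifest$seed[i]))
    names(subs) <- ids
    return(list(subjects = subs, manifest = manifest))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest$edf <- file.path(dir, paste0(ids, ".edf"))
  manifest$hypnogram <- file.path(dir, paste0(ids, ".hyp.csv"))
  for (i in seq_along(ids)) {
    sub <- generate_recording(cfg, ids[i], cohorts[i], seed = manifest$seed[i])
    write_edf(sub$recording, manifest$edf[i])
    write_hypnogram(sub$recording$hypnogram, manifest$hypnogram[i])
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE)
  manifest
}
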