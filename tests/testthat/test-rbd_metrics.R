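mk_ecg_rows <- function(stage, ...) {
  n <- length(stage)
  base <- tibble::tibble(epoch = seq_len(n) - 1L, stage = stage,
                         meanRR = 800, SDNN = 50, LFpeak = 0.1, HFpeak = 0.25,
                         SampEn = 1.5, IrrIndex = 3, OriginCount = 100,
                         LFHF = 2)
  mod <- list(...)
  for (nm in names(mod)) base[[nm]] <- mod[[nm]]
  base
}

test_that("ECG subject metrics reduce to stage-conditional means and ratios", {
  st <- rep(c("NREM", "REM"), each = 10)
  m <- ecg_subject_metrics(mk_ecg_rows(st))
  expect_equal(unname(m[c("RR_Index", "LFHF_Index")]), c(1, 1))
  expect_equal(unname(m["Ratio_NREM"]), 1)

  st2 <- c(rep("NREM", 600), rep("REM", 120))
  expect_equal(unname(ecg_subject_metrics(mk_ecg_rows(st2))["Ratio_NREM"]), 5)

  # REM-specific RR shortening of 10% -> RR_Index ~ 0.9
  rr <- ifelse(st == "REM", 720, 800)
  m3 <- ecg_subject_metrics(mk_ecg_rows(st, meanRR = rr))
  expect_equal(unname(m3["RR_Index"]), 0.9)

  # no REM -> REM-dependent metrics are sentinels
  m4 <- ecg_subject_metrics(mk_ecg_rows(rep("NREM", 10)))
  expect_true(is.na(m4["RR_REM_Std"]))
  expect_true(is.na(m4["Ratio_NREM"]))
  # epoch order is irrelevant
  sh <- sample(length(st))
  rows <- mk_ecg_rows(st, meanRR = rr)
  expect_equal(ecg_subject_metrics(rows[sh, ]), m3)
})

# EMG with a prescribed per-second RMS envelope inside short REM bouts so the
# rolling-minimum correction sees true atonic floors
env_emg <- function(env_uv, fs = 200, seed = 1) {
  set.seed(seed)
  x <- rnorm(length(env_uv) * fs) * rep(env_uv, each = fs)
  signal_trace(x, fs, "EMG")
}

test_that("atonia index hits its definitional extremes and mixtures", {
  # 2-epoch NREM (quiet) / 2-epoch REM alternation, 20 cycles
  stages <- rep(rep(c("NREM", "REM"), each = 2), 20)
  hyp <- hypnogram(stages)
  sec <- rep(stages, each = 30)

  atonic <- ifelse(sec == "REM", 0.05, 0.05)
  expect_equal(atonia_index(env_emg(atonic), hyp, "REM"), 1)

  tonic <- ifelse(sec == "REM", 12, 0.05)   # loud REM inside quiet NREM
  expect_lt(atonia_index(env_emg(tonic), hyp, "REM"), 0.05)

  set.seed(2)
  mix <- ifelse(sec == "REM" & stats::runif(length(sec)) < 0.3, 12, 0.05)
  ai <- atonia_index(env_emg(mix), hyp, "REM")
  expect_lt(abs(ai - 0.7), 0.08)

  # absent stage -> sentinel
  expect_true(is.na(atonia_index(env_emg(atonic), hypnogram(rep("NREM", 80)),
                                 "REM")))
})

test_that("atonia index is non-increasing in the tonic fraction", {
  stages <- rep(rep(c("NREM", "REM"), each = 2), 15)
  hyp <- hypnogram(stages)
  sec <- rep(stages, each = 30)
  set.seed(4)
  u <- stats::runif(length(sec))
  ais <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(frac) {
    env <- ifelse(sec == "REM" & u < frac, 12, 0.05)
    atonia_index(env_emg(env, seed = 9), hyp, "REM")
  }, numeric(1))
  expect_true(all(diff(ais) <= 1e-9))
})

test_that("the spectral exponent separates white from 1/f EMG", {
  hyp <- hypnogram(rep("REM", 12))
  set.seed(6)
  white <- signal_trace(rnorm(12 * 6000), 200, "EMG")
  expect_lt(abs(fractal_exponent(white, hyp, "REM")), 0.1)

  pink <- signal_trace(rbdscreen:::shaped_noise(12 * 6000, 200, 5, 99,
                                                slope = -1), 200, "EMG")
  b <- fractal_exponent(pink, hyp, "REM")
  expect_lt(abs(b - (-1)), 0.15)
})

test_that("EMG subject metrics respond to the RSWA switch and to dilution", {
  cfg <- synth_config(night_epochs = 80, seed = 51)
  hyp <- generate_hypnogram(cfg, 51)
  emg_hc <- filter_emg(generate_emg(hyp, cfg, seed = 52, rswa_effect = 0))
  emg_rbd <- filter_emg(generate_emg(hyp, cfg, seed = 52, rswa_effect = 1))
  m_hc <- emg_subject_metrics(emg_hc, hyp)
  m_rbd <- emg_subject_metrics(emg_rbd, hyp)
  expect_lt(m_rbd[["AtoniaIndex_REM"]], m_hc[["AtoniaIndex_REM"]])
  expect_gt(m_rbd[["MotorActivity_REM"]], m_hc[["MotorActivity_REM"]])

  # identical REM/NREM signal statistics -> ratio metrics near 1
  cfg_flat <- synth_config(night_epochs = 80, seed = 51,
                           emg_tone_by_stage = c(W = 5, NREM = 5, REM = 5))
  m_flat <- emg_subject_metrics(
    filter_emg(generate_emg(hyp, cfg_flat, seed = 53, rswa_effect = 0)), hyp)
  expect_lt(abs(m_flat[["FractalExponentRatio"]] - 1), 0.05)

  # relabelling REM as NREM dilutes the atonia contrast toward 1
  st <- as.character(hyp$stages)
  st_swap <- ifelse(st == "REM", "NREM", st)
  st_swap[which(st == "NREM")[1:20]] <- "REM"   # keep some REM labelled
  m_dil <- emg_subject_metrics(emg_rbd, hypnogram(st_swap))
  expect_lt(abs(m_dil[["AtoniaIndexRatio"]] - 1),
            abs(m_rbd[["AtoniaIndexRatio"]] - 1) + 0.2)

  # all-REM hypnogram: ratio metrics are sentinels
  m_all <- emg_subject_metrics(emg_rbd, hypnogram(rep("REM", 80)))
  expect_true(is.na(m_all[["AtoniaIndexRatio"]]))
  expect_true(is.na(m_all[["FractalExponentRatio"]]))
})

test_that("metrics from a perfect predicted hypnogram equal manual metrics", {
  co <- tiny_cohort()
  cc <- co$caches[[1]]
  manual <- subject_metric_row(cc)
  same <- subject_metric_row(cc, hyp = cc$hypnogram)
  expect_equal(manual, same)
})
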