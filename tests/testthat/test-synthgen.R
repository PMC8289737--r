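test_that("the Markov hypnogram respects its transition structure", {
  cst <- synth_config(night_epochs = 50, transition = diag(3))
  h <- generate_hypnogram(cst, 1)
  expect_equal(unique(as.character(h$stages)), "W")   # started (absorbed) in W

  cfg <- synth_config(night_epochs = 20000)
  h2 <- generate_hypnogram(cfg, 5)
  emp <- table(factor(as.character(h2$stages), c("W", "NREM", "REM"))) / 20000
  ev <- eigen(t(cfg$transition))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  expect_true(all(abs(as.numeric(emp) - stat) < 0.02))

  expect_identical(as.character(generate_hypnogram(cfg, 9)$stages),
                   as.character(generate_hypnogram(cfg, 9)$stages))
  expect_error(synth_config(transition = matrix(1, 3, 3)), "stochastic")
})

test_that("generated ECG carries the prescribed beat train and HRV contrast", {
  cfg <- constant_stage_cfg(hr = 60, night_epochs = 4, seed = 3)
  sim <- generate_ecg(generate_hypnogram(cfg, 3), cfg, seed = 3)
  pk <- pan_tompkins(filter_ecg(sim$trace))
  expect_equal(nrow(pk), length(sim$peaks_s))

  # HC: LF/HF higher in REM than NREM epochs, attenuated by the RSWA switch
  cfg2 <- synth_config(night_epochs = 240, seed = 7)
  contrast <- function(rswa, seed) {
    hyp <- generate_hypnogram(cfg2, seed)
    sim <- generate_ecg(hyp, cfg2, seed = seed + 1, rswa_effect = rswa)
    em <- ecg_epoch_matrix(filter_ecg(sim$trace), hyp, smooth = FALSE)
    median(em$LFHF[em$stage == "REM"], na.rm = TRUE) -
      median(em$LFHF[em$stage == "NREM"], na.rm = TRUE)
  }
  seeds <- c(61, 62, 73)   # draws with both stages well represented
  d_hc <- vapply(seeds, function(s) contrast(0, s), numeric(1))
  d_rbd <- vapply(seeds, function(s) contrast(1, s), numeric(1))
  expect_gt(median(d_hc), 0)
  expect_lt(median(d_rbd), median(d_hc))
})

test_that("stage-conditional RR variability matches the generator targets", {
  cfg <- synth_config(night_epochs = 240, seed = 17)
  hyp <- generate_hypnogram(cfg, 17)
  sim <- generate_ecg(hyp, cfg, seed = 18)
  rr <- diff(sim$peaks_s) * 1000
  st <- as.character(hyp$stages)[pmin(floor(sim$peaks_s[-1] / 30) + 1,
                                      length(hyp$stages))]
  hr_by <- numeric(0)
  for (s in c("W", "NREM", "REM")) {
    if (sum(st == s) < 200) next
    expect_lt(abs(stats::sd(rr[st == s]) - cfg$sdnn_by_stage[[s]]) /
                cfg$sdnn_by_stage[[s]], 0.2)
    hr_by[s] <- 60000 / mean(rr[st == s])
  }
  # absolute rate carries a subject offset; the stage ordering must hold
  if (all(c("W", "NREM", "REM") %in% names(hr_by))) {
    expect_gt(hr_by[["W"]], hr_by[["REM"]])
    expect_gt(hr_by[["REM"]], hr_by[["NREM"]])
  }
})

test_that("EOG deflections make REM epochs detectable; rate 0 removes them", {
  cfg <- synth_config(night_epochs = 240, seed = 23)
  hyp <- generate_hypnogram(cfg, 62)
  eog <- filter_eog(generate_eog(hyp, cfg, seed = 24))
  fe <- eog_epoch_features(eog, hyp)
  rem <- fe$MaxPeak[fe$stage == "REM"]; nrem <- fe$MaxPeak[fe$stage == "NREM"]
  auc <- mean(outer(rem, nrem, ">") + 0.5 * outer(rem, nrem, "=="))
  expect_gt(auc, 0.9)

  cfg0 <- synth_config(night_epochs = 120, rem_eog_event_rate = 0, seed = 23)
  eog0 <- filter_eog(generate_eog(hyp, cfg0, seed = 24))
  fe0 <- eog_epoch_features(eog0, hyp)
  p <- stats::wilcox.test(fe0$Coastline[fe0$stage == "REM"],
                          fe0$Coastline[fe0$stage == "NREM"])$p.value
  expect_gt(p, 0.01)
})

test_that("EMG tone scales homogeneously and RSWA moves the atonia index", {
  cfg <- synth_config(night_epochs = 120, seed = 33)
  hyp <- generate_hypnogram(cfg, 33)
  emg0 <- generate_emg(hyp, cfg, seed = 34, rswa_effect = 0)
  expect_gte(atonia_index(filter_emg(emg0), hyp, "REM"), 0.9)
  emg1 <- generate_emg(hyp, cfg, seed = 34, rswa_effect = 1)
  expect_lte(atonia_index(filter_emg(emg1), hyp, "REM"), 0.5)

  cfg2 <- synth_config(night_epochs = 120, seed = 33,
                       emg_tone_by_stage = 2 * cfg$emg_tone_by_stage)
  emg2 <- generate_emg(hyp, cfg2, seed = 34, rswa_effect = 0)
  r0 <- emg_epoch_features(emg0, hyp)$RMS
  r2 <- emg_epoch_features(emg2, hyp)$RMS
  expect_equal(r2, 2 * r0, tolerance = 1e-8)
})

test_that("cohort generation is reproducible to the EDF byte level", {
  cfg <- synth_config(n_hc = 1, n_rbd = 1, night_epochs = 20, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_cohort(cfg, d1)
  m2 <- generate_cohort(cfg, d2)
  for (i in seq_len(nrow(m1)))
    expect_identical(readBin(m1$edf[i], "raw", 5e7),
                     readBin(m2$edf[i], "raw", 5e7))
  expect_true(file.exists(file.path(d1, "manifest.json")))

  # round-trip through EDF preserves the signals within quantisation
  rec <- read_edf(m1$edf[1], c(ECG = "ECG", EOG = "EOG", EMG = "EMG"))
  fresh <- generate_recording(cfg, m1$subject_id[1], m1$cohort[1],
                              seed = m1$seed[1])
  for (m in c("ECG", "EOG", "EMG")) {
    orig <- fresh$recording$traces[[m]]$samples
    qstep <- 2 * max(abs(orig)) * (1 + 1e-6) / 65535
    expect_lt(max(abs(rec$traces[[m]]$samples - orig)), qstep + 1e-9)
  }
})

test_that("a single-cohort run propagates the single-class refusal", {
  mets <- tiny_metrics()
  only_hc <- mets[mets$cohort == "HC", ]
  expect_error(train_detector(only_hc, detection_config("E1_emg")), "single")
  expect_error(detect_cv(only_hc, detection_config("E1_emg")), "both cohorts")
})
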