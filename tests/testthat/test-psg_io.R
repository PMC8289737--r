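test_that("stage label mapping collapses R&K and AASM onto three states", {
  expect_equal(map_to_three_state(c("W", "N1", "N2", "N3", "R")),
               c("W", "NREM", "NREM", "NREM", "REM"))
  expect_equal(map_to_three_state(c("S1", "S4", "MT")),
               c("NREM", "NREM", "UNSCORED"))
  expect_equal(map_to_three_state(c("n2", "rem", "wake", "0")),
               c("NREM", "REM", "W", "W"))
  expect_equal(map_to_three_state("MOVEMENT"), "UNSCORED")
  # total and idempotent on its own outputs
  out <- map_to_three_state(c("W", "N2", "R", "junk", ""))
  expect_equal(map_to_three_state(out), out)
})

test_that("hypnogram files parse under each dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("epoch,stage", "0,W", "1,N1", "2,N2", "3,N3", "4,R"), f)
  h <- read_hypnogram(f, "csv")
  expect_equal(as.character(h$stages), c("W", "NREM", "NREM", "NREM", "REM"))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("S1", "S4", "MT"), f2)
  expect_warning(h2 <- read_hypnogram(f2, "capstyle"), "UNSCORED")
  expect_equal(as.character(h2$stages), c("NREM", "NREM", "UNSCORED"))

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f3)
  expect_error(read_hypnogram(f3, "csv"), "empty")

  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0,W", "20,N2"), f4)   # 20-s epochs: no resampling rule
  expect_error(read_hypnogram(f4, "massstyle"), "30-s")
  f5 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("60,W", "90,N2"), f5)
  h5 <- read_hypnogram(f5, "massstyle")
  expect_equal(h5$start_offset_s, 60)
})

test_that("EDF round-trip preserves rates exactly and samples to quantisation", {
  fs <- 200
  t <- seq(1 / fs, 10, by = 1 / fs)
  tr_ecg <- signal_trace(800 * sin(2 * pi * 7 * t), fs, "ECG", "ecgch")
  tr_eog <- signal_trace(150 * sin(2 * pi * 1 * t), fs, "EOG", "eogch")
  tr_emg <- signal_trace(30 * rnorm(length(t)), fs, "EMG", "emgch")
  rec <- recording("subj42", list(tr_ecg, tr_eog, tr_emg), cohort = "HC")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f, c(ECG = "ecgch", EOG = "eogch", EMG = "emgch"))
  expect_equal(back$subject_id, "subj42")
  for (m in c("ECG", "EOG", "EMG")) {
    expect_equal(back$traces[[m]]$rate_hz, fs)
    orig <- rec$traces[[m]]$samples
    qstep <- 2 * max(abs(orig)) * (1 + 1e-6) / 65535
    expect_lt(max(abs(back$traces[[m]]$samples - orig)), qstep)
  }
})

test_that("read_edf names available channels when a mapping is missing", {
  rec <- recording("s", list(sine_trace(5, 2, modality = "ECG")))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  expect_error(read_edf(f, c(EMG = "EMG-submental")), "available.*ECG")
})

test_that("resampling preserves duration and spectral content", {
  fs0 <- 256
  t <- seq(1 / fs0, 10, by = 1 / fs0)
  tr <- signal_trace(sin(2 * pi * 5 * t), fs0, "EOG")
  rs <- resample_trace(tr, 200)
  expect_equal(rs$rate_hz, 200)
  expect_equal(length(rs$samples), 2000)
  sp <- stats::spec.pgram(stats::ts(rs$samples, frequency = 200), plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 5), 0.2)

  same <- resample_trace(tr, fs0)
  expect_identical(length(same$samples), length(tr$samples))

  tr100 <- signal_trace(rnorm(1000), 100, "EMG")
  up <- resample_trace(tr100, 200)
  expect_lte(abs(length(up$samples) - 2000), 1)
})

test_that("epoch slices partition the covered span into 30-s blocks", {
  tr <- signal_trace(rnorm(3 * 30 * 200), 200, "EOG")
  hyp <- hypnogram(c("W", "NREM", "REM"))
  sl <- epoch_slices(tr, hyp)
  expect_equal(sl$from, c(0L, 6000L, 12000L))
  expect_equal(sl$to, c(6000L, 12000L, 18000L))
  expect_equal(sum(sl$to - sl$from), 30 * 200 * 3)

  short <- signal_trace(rnorm(3 * 30 * 200 - 5 * 200), 200, "EOG")
  expect_warning(sl2 <- epoch_slices(short, hyp), "partial")
  expect_equal(nrow(sl2), 2)

  expect_equal(nrow(epoch_slices(tr, hypnogram(character(0)))), 0)
  long <- hypnogram(rep("NREM", 6))
  expect_error(epoch_slices(tr, long), "more than one epoch")
})

test_that("non-finite samples are repaired, not propagated", {
  x <- c(1, 2, NA, 4, Inf, 6)
  expect_warning(tr <- signal_trace(x, 10, "EMG"), "repaired")
  expect_true(all(is.finite(tr$samples)))
  expect_equal(tr$samples[3], 3)
})
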