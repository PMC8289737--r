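test_that("time-domain features match hand counts and the brute-force oracle", {
  td <- time_domain_hrv(make_rr(c(800, 740, 795, 800)))
  expect_equal(unname(td["NN50"]), 2)
  expect_equal(unname(td["pNN50"]), 2 / 3)

  cst <- time_domain_hrv(make_rr(rep(800, 10)))
  expect_equal(unname(cst[c("SDNN", "RMSSD", "SDSD")]), c(0, 0, 0))

  set.seed(42)
  for (i in 1:100) {
    rr <- stats::runif(sample(5:80, 1), 500, 1400)
    got <- time_domain_hrv(make_rr(rr))
    want <- oracle_td(rr)
    for (nm in names(want))
      expect_equal(unname(got[nm]), want[[nm]], tolerance = 1e-9)
  }

  expect_true(all(is.na(time_domain_hrv(make_rr(numeric(0))))))
})

test_that("invalid intervals are excluded but never interpolated", {
  rr <- make_rr(c(800, 800, 3000, 800, 800),
                valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  td <- time_domain_hrv(rr)
  expect_equal(unname(td["meanRR"]), 800)
  expect_equal(unname(td["SDNN"]), 0)
})

test_that("spectral HRV localises single-band modulation", {
  mk_mod <- function(f_mod, depth = 60) {
    t <- 0; rr <- numeric(0); on <- numeric(0)
    while (t < 330) {
      r <- 1000 + depth * sin(2 * pi * f_mod * t)
      on <- c(on, t); rr <- c(rr, r); t <- t + r / 1000
    }
    make_rr(rr, onset_s = on)
  }
  lf <- freq_domain_hrv(mk_mod(0.10))
  expect_lt(abs(lf[["LFpeak"]] - 0.10), 0.02)
  expect_gt(lf[["LFHF"]], 5)
  hf <- freq_domain_hrv(mk_mod(0.25))
  expect_lt(abs(hf[["HFpeak"]] - 0.25), 0.02)
  expect_lt(hf[["LFHF"]], 0.2)
  expect_equal(lf[["nLF"]] + lf[["nHF"]], 1)
  expect_equal(hf[["nLF"]] + hf[["nHF"]], 1)
  # insufficient coverage -> sentinel
  expect_true(all(is.na(freq_domain_hrv(make_rr(rep(800, 20))))))
})

test_that("nonlinear features behave at their analytic anchors", {
  cst <- nonlinear_hrv(make_rr(rep(800, 40)))
  expect_equal(unname(cst[c("SampEn", "PoincareSD1", "PoincareSD2")]),
               c(0, 0, 0))

  alt <- rep(c(700, 900), 30)
  nl <- nonlinear_hrv(make_rr(alt))
  bits <- as.integer(alt > stats::median(alt))
  expect_equal(unname(nl["LZ"]), oracle_lz76(bits))
  expect_lt(nl[["PDa"]], 0)   # strict alternation: negative lag-1 autocorr

  set.seed(5)
  wins <- 0
  for (k in 1:10) {
    iid <- stats::runif(300, 700, 1100)
    tt <- seq_len(300) * 0.8
    sine <- 900 + stats::sd(iid) * sqrt(2) * sin(2 * pi * 0.1 * tt) +
      rnorm(300, 0, 5)
    d_iid <- nonlinear_hrv(make_rr(iid))[["DET"]]
    d_sine <- nonlinear_hrv(make_rr(sine))[["DET"]]
    wins <- wins + (d_iid < d_sine)
  }
  expect_gte(wins, 9)   # deterministic structure raises determinism

  expect_true(all(is.na(nonlinear_hrv(make_rr(rep(800, 5))))))
})

test_that("sample/approximate entropy track an independent naive oracle", {
  naive_sampen <- function(x, m = 2, r) {
    n <- length(x); B <- 0; A <- 0
    for (i in 1:(n - m)) for (j in 1:(n - m)) {
      if (j <= i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
    -log(A / B)
  }
  set.seed(9)
  x <- stats::runif(120, 700, 1100)
  r <- 0.2 * stats::sd(x)
  got <- nonlinear_hrv(make_rr(x))[["SampEn"]]
  expect_equal(got, naive_sampen(x, 2, r), tolerance = 1e-12)
})

test_that("Lorenz regularity features follow their binning rules", {
  reg <- regularity_features(make_rr(rep(800, 50)))
  expect_equal(unname(reg["IrrIndex"]), 0)
  expect_equal(unname(reg["PACEv"]), 0)
  expect_gt(reg[["OriginCount"]], 0)

  # premature beat (-120 ms) with compensatory pause (+130 ms)
  rr <- c(rep(800, 10), 680, 810, rep(800, 10))
  expect_gte(regularity_features(make_rr(rr))[["PACEv"]], 1)

  set.seed(13)
  irr <- regularity_features(make_rr(stats::rnorm(100, 800, 100)))
  expect_gt(irr[["IrrIndex"]], 10)
})

test_that("waveform shape, rate flags and elapsed time are exact", {
  fs <- 200
  t <- seq(1 / fs, 30, by = 1 / fs)
  sh <- ecg_shape_features(sin(2 * pi * 10 * t), fs)
  expect_equal(unname(sh["ZCI"]), 20, tolerance = 0.01)
  expect_equal(unname(sh["mZCI"]), 0.05, tolerance = 0.001)
  sh2 <- ecg_shape_features(rep(3, 6000), fs)
  expect_equal(unname(sh2[c("ZCI", "Ampstdsqi")]), c(0, 0))
  shx <- ecg_shape_features(2 * sin(2 * pi * 10 * t), fs)
  expect_equal(shx[["AmpMean"]], 2 * sh[["AmpMean"]])
  expect_equal(shx[["ZCI"]], sh[["ZCI"]])

  expect_equal(unname(rate_flags(make_rr(rep(500, 10)))), c(1, 0))
  expect_equal(unname(rate_flags(make_rr(rep(1200, 10)))), c(0, 1))
  expect_equal(unname(rate_flags(make_rr(rep(750, 10)))), c(0, 0))

  et <- elapsed_time_features(c(0L, 120L, 959L), 960L)
  expect_equal(et$HoursRec, c(0, 1, 959 * 30 / 3600))
  expect_equal(et$HoursRecEnd[3], 0)
  expect_error(elapsed_time_features(960L, 960L), "range")
})

test_that("epoch matrix smoothing is a 5-epoch NA-aware moving average", {
  m <- matrix(c(rep(0, 10), rep(10, 10)), ncol = 1)
  sm <- rbdscreen:::smooth_columns(m, 5L)
  # step transitions over exactly 5 epochs: 0,...,0,2,4,6,8,10,10,...
  expect_equal(sm[8:13, 1], c(0, 2, 4, 6, 8, 10))
  # shrinking edges: first value is mean of first 3
  expect_equal(sm[1, 1], mean(m[1:3, 1]))
  expect_equal(sm[20, 1], mean(m[18:20, 1]))
  m2 <- matrix(c(NA, 1, 2, 3, NA, 5), ncol = 1)
  sm2 <- rbdscreen:::smooth_columns(m2, 5L)
  expect_equal(sm2[1, 1], 1.5)  # mean of the available 1, 2
})

test_that("a constant-rate night yields a zero-variance smoothed bank", {
  cfg <- constant_stage_cfg(hr = 75, night_epochs = 12, sdnn = 0.5, seed = 2)
  hyp <- generate_hypnogram(cfg, 2)
  sim <- generate_ecg(hyp, cfg, seed = 2)
  em <- ecg_epoch_matrix(filter_ecg(sim$trace), hyp)
  expect_equal(nrow(em), 12)
  # RR variability is limited by the 5-ms detection grid (sd ~2 ms)
  expect_true(all(em$SDNN < 3))
  expect_lt(max(abs(em$meanRR - stats::median(em$meanRR))), 1)
  expect_true(all(em$Tachy == 0) && all(em$Brady == 0))
})
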