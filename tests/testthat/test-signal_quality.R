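# pulse train of amplitude 1 mV each second over a constant background
# whose sqrt(2)*RMS is 1/10 mV -> SNR identically 20 dB, bypassing the
# wavelet decomposition through the injection hook
test_that("closed-form 20 dB case through the decomposition hook", {
  fs <- 128; n <- fs * 60
  hook <- function(x, fs_) {
    sig <- numeric(n); sig[seq(1, n, by = fs)] <- 1.0
    list(signal = sig, background = rep(1 / (10 * sqrt(2)), n))
  }
  e <- ecg_record(stats::rnorm(n), fs)
  s <- compute_snr(e, qc_config(decompose = hook))
  expect_equal(length(s$snr_db), n)
  expect_equal(unique(round(s$snr_db, 9)), 20)
})

test_that("SNR is invariant to rescaling the input (linear decomposition)", {
  x <- make_clean_ecg(n_epochs = 4, fs = 128, seed = 8)
  e <- x$ecg
  s1 <- compute_snr(e, qc_config())
  for (c_scale in c(0.2, 3, 40)) {
    e2 <- ecg_record(e$samples * c_scale, e$fs)
    s2 <- compute_snr(e2, qc_config())
    expect_equal(s2$snr_db, s1$snr_db, tolerance = 1e-8)
  }
})

test_that("a background-free record sits at the clipping ceiling", {
  fs <- 128; n <- fs * 30
  hook <- function(x, fs_) list(signal = x, background = numeric(n))
  e <- ecg_record(sin(2 * pi * 10 * (0:(n - 1)) / fs), fs)
  s <- compute_snr(e, qc_config(decompose = hook, noise_window_s = 10))
  expect_true(all(s$snr_db == 80))
})

test_that("clean synthetic ECG passes QC with no epochs rejected", {
  x <- make_clean_ecg(n_epochs = 10, fs = 256, seed = 1)
  q <- qc_record(x$ecg)
  expect_false(any(q$epoch_rejected))
  expect_false(q$recording_excluded)
  expect_gt(min(q$snr$snr_db), qc_config()$snr_threshold_db)
})

test_that("epoch rejection boundary semantics are >= 50% and strict < 5 dB", {
  fs <- 10; spe <- 30 * fs
  mk <- function(db) {
    structure(list(snr_db = db, a_signal = db, a_noise = db, fs = fs),
              class = "snr_series")
  }
  # exactly half below: rejected (inclusive)
  half <- c(rep(4.9, spe / 2), rep(5.1, spe / 2))
  q <- classify_epochs(mk(half), cfg = qc_config())
  expect_true(q$epoch_rejected[1])
  # all exactly at 5.0 dB: not rejected (strict <)
  q2 <- classify_epochs(mk(rep(5.0, spe)), cfg = qc_config())
  expect_false(q2$epoch_rejected[1])
  # comfortable signal: never rejected
  q3 <- classify_epochs(mk(rep(30, spe * 4)), cfg = qc_config())
  expect_false(any(q3$epoch_rejected))
  # one sample under half: retained
  almost <- c(rep(4.9, spe / 2 - 1), rep(5.1, spe / 2 + 1))
  expect_false(classify_epochs(mk(almost), cfg = qc_config())$epoch_rejected[1])
})

test_that("recording exclusion boundary is inclusive at 10%", {
  mk <- function(nrej, ntot) {
    structure(list(epoch_rejected = c(rep(TRUE, nrej),
                                      rep(FALSE, ntot - nrej)),
                   fraction_rejected = NA, recording_excluded = NA,
                   config = qc_config()),
              class = "quality_report")
  }
  expect_true(assess_recording(mk(10, 100))$recording_excluded)
  expect_false(assess_recording(mk(9, 100))$recording_excluded)
  q0 <- assess_recording(mk(0, 100))
  expect_false(q0$recording_excluded)
  expect_equal(q0$fraction_rejected, 0)
})

test_that("added noise never increases the mean SNR", {
  x <- make_clean_ecg(n_epochs = 6, fs = 128, seed = 14)
  base <- x$ecg$samples
  set.seed(99)
  noise <- stats::rnorm(length(base))
  prev <- Inf
  for (sd_n in c(0, 0.05, 0.15, 0.4, 1.0)) {
    e <- ecg_record(base + sd_n * noise, x$ecg$fs)
    m <- mean(compute_snr(e, qc_config())$snr_db)
    expect_lte(m, prev + 1e-9)
    prev <- m
  }
})

test_that("noise in [60, 90) s flags only epochs overlapping that window", {
  x <- make_clean_ecg(n_epochs = 10, fs = 256, seed = 1)
  cfg <- ecg_synth_config(fs = 256, noise_segments = list(c(60, 90, 3)))
  e <- synthesize_ecg(x$rpeaks, cfg, duration_s = 300, seed = 5)
  q <- qc_record(e)
  rej <- which(q$epoch_rejected)          # 1-based epochs
  expect_true(3 %in% rej)                 # the 60-90 s epoch itself
  # at most one adjacent epoch of spillover (10-s noise window)
  expect_true(all(rej %in% c(2, 3, 4)))
})

test_that("a-trous decomposition reconstructs additively and is linear", {
  set.seed(31)
  x <- stats::rnorm(4096)
  d <- atrous_decompose(x, fs = 128, band = c(5, 32))
  expect_equal(d$signal + d$background, x, tolerance = 1e-10)
  d2 <- atrous_decompose(3 * x, fs = 128, band = c(5, 32))
  expect_equal(d2$signal, 3 * d$signal, tolerance = 1e-10)
  # band selectivity: a 10 Hz tone lands in the signal component
  tone <- sin(2 * pi * 10 * (0:4095) / 128)
  dt <- atrous_decompose(tone, 128, c(5, 32))
  expect_gt(stats::var(dt$signal), 10 * stats::var(dt$background))
  # a 0.2 Hz drift lands in the background
  drift <- sin(2 * pi * 0.2 * (0:4095) / 128)
  dd <- atrous_decompose(drift, 128, c(5, 32))
  expect_gt(stats::var(dd$background), 10 * stats::var(dd$signal))
})

test_that("records shorter than the noise window are refused", {
  e <- ecg_record(stats::rnorm(100), 100)        # 1 s
  expect_error(compute_snr(e, qc_config()), "shorter than the noise window")
})
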