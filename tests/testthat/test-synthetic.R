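test_that("degenerate and deterministic hypnogram simulation", {
  cfg <- hypnogram_model_config(transition = diag(5),
                                initial = c(0, 0, 1, 0, 0),
                                n_epochs = 50, seed = 4)
  h <- simulate_hypnogram(cfg)
  expect_true(all(h$labels == "N2"))

  cfg2 <- hypnogram_model_config(n_epochs = 500, seed = 9)
  expect_identical(simulate_hypnogram(cfg2)$labels,
                   simulate_hypnogram(cfg2)$labels)

  bad <- matrix(1 / 5, 5, 5); bad[1, 1] <- 0.5
  expect_error(hypnogram_model_config(transition = bad), "sum to 1")
})

test_that("long-run stage frequencies match the stationary distribution", {
  cfg <- hypnogram_model_config(n_epochs = 100000, seed = 17)
  h <- simulate_hypnogram(cfg)
  emp <- table(factor(h$labels, levels = STAGES_AASM5)) / length(h$labels)
  stat <- stationary_distribution(cfg$transition)
  expect_lt(max(abs(as.numeric(emp) - as.numeric(stat))), 0.01)
})

test_that("RR generator hits stage means and degenerates to a constant", {
  dyn0 <- stage_dynamics_config(stages = data.frame(
    stage = STAGES_AASM5, mean_rr = c(850, 950, 1000, 1050, 1050),
    sdnn = 0, lf_power = 0, hf_power = 0, resp_rate = 0.2))
  h <- hypnogram(rep("N3", 40))
  r <- simulate_rr_series(h, dyn0, seed = 1)
  rr <- rr_intervals(r)
  expect_lt(max(abs(rr - 1050)), 1e-6)

  # stage-conditional means within 2 SEM over long runs
  dyn <- stage_dynamics_config("default")
  h2 <- hypnogram(c(rep("N3", 30), rep("R", 30), rep("W", 30)))
  r2 <- simulate_rr_series(h2, dyn, seed = 2)
  rr2 <- rr_intervals(r2)
  mid <- r2$times_s[-1]
  for (blk in list(c("N3", 120, 870), c("R", 1020, 1770),
                   c("W", 1920, 2670))) {
    # interior of each run, clear of the 30-s cross-fade
    sel <- mid > as.numeric(blk[2]) & mid < as.numeric(blk[3])
    m <- dyn$stages[blk[1], "mean_rr"]
    sem <- dyn$stages[blk[1], "sdnn"] / sqrt(sum(sel))
    expect_gt(sum(sel), 500)
    expect_lt(abs(mean(rr2[sel]) - m), 2 * sem + 0.05 * m)
  }
})

test_that("generated LF/HF band powers match configuration", {
  dyn <- stage_dynamics_config(stages = data.frame(
    stage = STAGES_AASM5, mean_rr = 900, sdnn = sqrt(1200 + 300),
    lf_power = 1200, hf_power = 300, resp_rate = 0.25))
  h <- hypnogram(rep("R", 40))                  # 20 min of REM
  r <- simulate_rr_series(h, dyn, seed = 6)
  tg <- resample_tachogram(r, 4)
  w <- welch_psd(tg$rr_ms, 4, segment_s = 120)
  lf <- sum(w$psd[w$freq > 0.04 & w$freq <= 0.15]) * diff(w$freq[1:2])
  hf <- sum(w$psd[w$freq > 0.15 & w$freq <= 0.40]) * diff(w$freq[1:2])
  expect_lt(abs(lf / hf - 1200 / 300) / (1200 / 300), 0.25)
})

test_that("synthetic ECG places one pulse per beat at the right place", {
  h <- hypnogram(rep("N2", 4))
  r <- simulate_rr_series(h, stage_dynamics_config("easy"), seed = 3)
  cfg <- ecg_synth_config(fs = 256)
  e <- synthesize_ecg(r, cfg, duration_s = 120)
  tt <- (seq_along(e$samples) - 1) / e$fs
  for (tb in r$times_s[seq(1, length(r), by = 7)]) {
    win <- which(abs(tt - tb) <= 0.15)
    peak <- tt[win[which.max(e$samples[win])]]
    expect_lt(abs(peak - tb), 1 / e$fs + 1e-9)
  }
  # linearity: doubling the amplitude doubles the waveform
  cfg2 <- ecg_synth_config(fs = 256, qrs_amplitude = 2)
  e2 <- synthesize_ecg(r, cfg2, duration_s = 120)
  expect_equal(e2$samples, 2 * e$samples, tolerance = 1e-12)

  expect_error(ecg_synth_config(fs = 100, qrs_width_ms = 30), "qrs_width")
})

test_that("cohort generation balances strata and plants effects", {
  co <- simulate_cohort(4, n_epochs = 20, seed = 2)
  expect_equal(nrow(co$meta), 4)
  expect_equal(as.integer(table(co$meta$sex)), c(2, 2))

  co2 <- simulate_cohort(12, n_epochs = 40, base_accuracy = 0.9,
                         planted_effects = c(">60" = 0.2), seed = 3)
  acc <- vapply(co2$subjects, function(s) {
    mean(s$pred4 == collapse_stages(s$hypnogram$labels, "aasm5", 4))
  }, 0)
  old <- co2$meta$age_group == ">60"
  expect_gt(mean(acc[!old]), mean(acc[old]))

  expect_error(simulate_cohort(4, n_epochs = 20, base_accuracy = 0.9,
                               planted_effects = c(">60" = 0.1)),
               ">= 2 subjects per stratum")
  expect_error(simulate_cohort(8, n_epochs = 10,
                               planted_effects = c(zzz = 0.1),
                               base_accuracy = 0.9),
               "unknown planted-effect")
})

test_that("generators are deterministic and respect beat-time invariants", {
  h <- simulate_hypnogram(hypnogram_model_config(n_epochs = 60, seed = 12))
  r1 <- simulate_rr_series(h, seed = 7)
  r2 <- simulate_rr_series(h, seed = 7)
  expect_identical(r1$times_s, r2$times_s)
  expect_true(all(diff(r1$times_s) >= 0.3))
  e1 <- synthesize_ecg(r1, ecg_synth_config(
    fs = 128, noise_segments = list(c(0, 10, 0.1))), seed = 4)
  e2 <- synthesize_ecg(r1, ecg_synth_config(
    fs = 128, noise_segments = list(c(0, 10, 0.1))), seed = 4)
  expect_identical(e1$samples, e2$samples)
})
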