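# Minimal EDF writer for round-trip fixtures (the package itself never
# writes EDF). Signals: list of list(label=, samples=, phys_dim=, fs=).
write_edf_fixture <- function(path, signals, record_dur_s = 1,
                              date = "02.01.24", time = "23.30.00") {
  ns <- length(signals)
  nspr <- vapply(signals, function(s) as.integer(s$fs * record_dur_s), 0L)
  n_rec <- max(vapply(seq_along(signals), function(i) {
    ceiling(length(signals[[i]]$samples) / nspr[i])
  }, 0))
  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    paste0(x, strrep(" ", w - nchar(x)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("patient", 80); wr("recording", 80)
  wr(date, 8); wr(time, 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_rec, 8)
  wr(format(record_dur_s), 8); wr(ns, 4)
  for (s in signals) wr(s$label, 16)
  for (s in signals) wr("transducer", 80)
  for (s in signals) wr(s$phys_dim, 8)
  phys_min <- vapply(signals, function(s) min(s$samples) - 1e-6, 0)
  phys_max <- vapply(signals, function(s) max(s$samples) + 1e-6, 0)
  for (p in phys_min) wr(format(p, digits = 6), 8)
  for (p in phys_max) wr(format(p, digits = 6), 8)
  for (s in signals) wr("-32768", 8)
  for (s in signals) wr("32767", 8)
  for (s in signals) wr("", 80)
  for (v in nspr) wr(v, 8)
  for (s in signals) wr("", 32)
  # re-read the headers we actually wrote (format() rounds) for scaling
  pm_lo <- as.numeric(vapply(phys_min, function(p) pad(format(p, digits = 6), 8), ""))
  pm_hi <- as.numeric(vapply(phys_max, function(p) pad(format(p, digits = 6), 8), ""))
  for (r in seq_len(n_rec)) {
    for (i in seq_along(signals)) {
      idx <- ((r - 1) * nspr[i] + 1):(r * nspr[i])
      x <- signals[[i]]$samples[idx]
      x[is.na(x)] <- 0
      dig <- round((x - pm_lo[i]) / (pm_hi[i] - pm_lo[i]) * 65535 - 32768)
      writeBin(as.integer(pmax(pmin(dig, 32767), -32768)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

# ECG record with beats at known times (clean Ricker pulses)
make_clean_ecg <- function(n_epochs = 20, fs = 256, seed = 5,
                           regime = "default") {
  h <- simulate_hypnogram(hypnogram_model_config(n_epochs = n_epochs,
                                                 seed = seed))
  r <- simulate_rr_series(h, stage_dynamics_config(regime), seed = seed + 1)
  e <- synthesize_ecg(r, ecg_synth_config(fs = fs),
                      duration_s = 30 * n_epochs)
  list(hypnogram = h, rpeaks = r, ecg = e)
}

# greedy 1-1 beat matching within a tolerance; returns match stats
match_beats <- function(truth, detected, tol_s = 0.150) {
  used <- rep(FALSE, length(detected))
  err <- rep(NA_real_, length(truth))
  for (i in seq_along(truth)) {
    d <- abs(detected - truth[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_s) {
      used[j] <- TRUE
      err[i] <- detected[j] - truth[i]
    }
  }
  list(recall = mean(!is.na(err)),
       precision = sum(used) / max(1, length(detected)),
       mae_ms = mean(abs(err), na.rm = TRUE) * 1000)
}

# build prepared training subjects from the easy synthetic regime
make_training_cohort <- function(n_sub, n_ep, seed0 = 0,
                                 regime = "easy", permute = FALSE) {
  dyn <- stage_dynamics_config(regime)
  lapply(seq_len(n_sub), function(s_i) {
    hh <- simulate_hypnogram(
      hypnogram_model_config(n_epochs = n_ep, seed = seed0 + 100 + s_i))
    rr <- simulate_rr_series(hh, dyn, seed = seed0 + 200 + s_i)
    tg <- resample_tachogram(clean_rr(rr))
    ft <- compute_epoch_features(tg, n_epochs = n_ep, grid_start_s = 0)
    sub <- prepare_subject(assemble_inputs(tg, ft, context_epochs = 0), hh)
    if (permute) {
      set.seed(seed0 + 300 + s_i)
      sub$y <- sample(sub$y)
    }
    sub
  })
}

# independent brute-force metric computation used as the oracle
brute_force_metrics <- function(M) {
  n <- sum(M)
  k <- nrow(M)
  acc <- sum(diag(M)) / n
  pe <- 0
  for (i in seq_len(k)) pe <- pe + sum(M[i, ]) * sum(M[, i])
  pe <- pe / n^2
  kap <- (acc - pe) / (1 - pe)
  per <- list()
  for (i in seq_len(k)) {
    tp <- M[i, i]; fn <- sum(M[i, ]) - tp; fp <- sum(M[, i]) - tp
    tn <- n - tp - fn - fp
    per[[i]] <- c(
      se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  }
  list(accuracy = acc, kappa = kap, per_class = per)
}
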