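#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed, 50%-overlapping,
#' linearly detrended segments. Density normalization is such that the
#' integral of the PSD over frequency approximates the signal variance, so
#' band-integrated powers of an RR series come out in ms^2.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param segment_s Segment length in seconds (default: `length(x)/fs/4`,
#'   at least 30 s where possible).
#' @return `list(freq =, psd =)`.
#' @export
welch_psd <- function(x, fs, segment_s = NULL) {
  n <- length(x)
  if (is.null(segment_s)) segment_s <- max(30, n / fs / 4)
  nseg <- min(n, max(16L, round(segment_s * fs)))
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(win^2)
  nf <- nseg %/% 2L
  acc <- numeric(nf)
  tt <- seq_len(nseg)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    fit <- stats::lm.fit(cbind(1, tt), seg)       # linear detrend
    seg <- fit$residuals * win
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[2:(nf + 1L)]
  }
  psd <- acc / length(starts) / (u * fs)
  freq <- (1:nf) * fs / nseg
  list(freq = freq, psd = psd * 2)                # one-sided
}

.band_power <- function(w, band) {
  i <- which(w$freq > band[1] & w$freq <= band[2])
  if (!length(i)) return(0)
  df <- w$freq[2] - w$freq[1]
  sum(w$psd[i]) * df
}

# HRV frequency bands (Hz), task-force conventions
LF_BAND <- c(0.04, 0.15)
HF_BAND <- c(0.15, 0.40)

#' Per-epoch heart-rate and HRV features
#'
#' For each 30-s epoch of the grid: time-domain features (mean HR, SDNN,
#' RMSSD of the resampled RR series) from the epoch window, and spectral
#' features (LF 0.04-0.15 Hz and HF 0.15-0.40 Hz band powers plus their
#' ratio) from a 5-min window centered on the epoch — the shortest
#' conventional window for LF estimation. Epochs not covered by the
#' tachogram get `NA` features rather than fabricated values.
#'
#' @param t A [tachogram()].
#' @param n_epochs Number of 30-s epochs on the grid; defaults to the
#'   epochs fully covered by the tachogram (grid starts at the tachogram
#'   origin).
#' @param grid_start_s Start time of epoch 0 (defaults to the tachogram
#'   origin).
#' @param spectral_window_s Width of the centered spectral window.
#' @return A data.frame of class `"epoch_features"`, one row per epoch:
#'   `epoch`, `mean_hr`, `sdnn`, `rmssd`, `lf_power`, `hf_power`,
#'   `lf_hf_ratio`, `resp_rate`, `in_bed`.
#' @export
compute_epoch_features <- function(t, n_epochs = NULL, grid_start_s = NULL,
                                   spectral_window_s = 300) {
  stopifnot(inherits(t, "tachogram"))
  tt <- tachogram_times(t)
  if (is.null(grid_start_s)) grid_start_s <- t$origin_s
  if (is.null(n_epochs)) {
    n_epochs <- max(1L, floor((max(tt) - grid_start_s) / 30))
  }
  fs <- t$rate_hz
  res <- data.frame(epoch = seq_len(n_epochs) - 1L)
  res$mean_hr <- NA_real_; res$sdnn <- NA_real_; res$rmssd <- NA_real_
  res$lf_power <- NA_real_; res$hf_power <- NA_real_
  res$lf_hf_ratio <- NA_real_; res$resp_rate <- NA_real_
  res$in_bed <- TRUE
  for (i in seq_len(n_epochs)) {
    e0 <- grid_start_s + 30 * (i - 1); e1 <- e0 + 30
    idx <- which(tt >= e0 & tt < e1)
    if (length(idx) < 2) next                      # epoch outside tachogram
    rr <- t$rr_ms[idx]
    res$mean_hr[i] <- 60000 / mean(rr)
    res$sdnn[i] <- stats::sd(rr)
    res$rmssd[i] <- sqrt(mean(diff(rr)^2))
    w0 <- max(min(tt), (e0 + e1) / 2 - spectral_window_s / 2)
    widx <- which(tt >= w0 & tt < w0 + spectral_window_s)
    if (length(widx) >= 64) {
      w <- welch_psd(t$rr_ms[widx], fs, segment_s = spectral_window_s / 2.5)
      lf <- .band_power(w, LF_BAND); hf <- .band_power(w, HF_BAND)
      res$lf_power[i] <- lf
      res$hf_power[i] <- hf
      res$lf_hf_ratio[i] <- if (hf > 0) lf / hf else NA_real_
      res$resp_rate[i] <- .dominant_hf_freq(w)
    }
  }
  res$mean_hr[res$mean_hr < 30 | res$mean_hr > 220] <- NA_real_
  class(res) <- c("epoch_features", "data.frame")
  res
}

# dominant frequency in the HF band, or NA when no energy rises above
# the spectral floor (respiratory sinus arrhythmia absent)
.dominant_hf_freq <- function(w, floor_ratio = 3) {
  i <- which(w$freq > HF_BAND[1] & w$freq <= HF_BAND[2])
  if (!length(i)) return(NA_real_)
  p <- w$psd[i]
  if (max(p) <= 1e-8) return(NA_real_)   # below numerical noise: no RSA
  med <- stats::median(w$psd[w$psd > 0])
  if (!is.finite(med) || med == 0) return(NA_real_)
  if (max(p) < floor_ratio * med) return(NA_real_)
  w$freq[i[which.max(p)]]
}

#' ECG-derived respiration rate per epoch
#'
#' Estimates breathing from respiratory sinus arrhythmia: the respiration
#' rate of an epoch is the dominant frequency of the RR series in the HF
#' band (0.15-0.40 Hz), measured on a 5-min window centered on the epoch.
#' Windows without HF energy above the spectral floor give `NA`.
#'
#' @param t A [tachogram()].
#' @inheritParams compute_epoch_features
#' @return Numeric vector of per-epoch respiration rates (Hz).
#' @export
derive_respiration <- function(t, n_epochs = NULL, grid_start_s = NULL,
                               spectral_window_s = 300) {
  compute_epoch_features(t, n_epochs, grid_start_s,
                         spectral_window_s)$resp_rate
}

#' In-bed score from a body-position time series
#'
#' An epoch is scored in-bed unless its modal position is `"upright"`.
#' With no position channel every epoch is scored in-bed, with a warning.
#'
#' @param position Character vector of position samples in
#'   \{supine, lateral_left, lateral_right, prone, upright\}, or `NULL`.
#' @param position_times_s Sample times (s) matching `position`.
#' @param n_epochs Number of 30-s epochs (epoch 0 starts at t = 0).
#' @return Logical vector, one value per epoch.
#' @export
in_bed_score <- function(position, position_times_s = NULL, n_epochs) {
  ok <- c("supine", "lateral_left", "lateral_right", "prone", "upright")
  if (is.null(position)) {
    warning("no position channel: scoring all epochs in-bed")
    return(rep(TRUE, n_epochs))
  }
  bad <- setdiff(unique(position), ok)
  if (length(bad)) stop("unknown position category: ", paste(bad, collapse = ", "))
  if (is.null(position_times_s)) {
    position_times_s <- seq(0, by = 30, length.out = length(position))
  }
  vapply(seq_len(n_epochs), function(i) {
    e0 <- 30 * (i - 1)
    idx <- which(position_times_s >= e0 & position_times_s < e0 + 30)
    if (!length(idx)) return(TRUE)
    tab <- table(position[idx])
    names(tab)[which.max(tab)] != "upright"
  }, TRUE)
}

#' Assemble the model input tensor
#'
#' Packs, for every epoch, the tachogram samples of the epoch plus
#' `context_epochs` epochs of context on each side (zero-padded with a
#' mask channel at the recording edges), together with the scalar epoch
#' features broadcast along time. Channels, in order: RR (seconds,
#' centered at 1.0), mask (1 = observed), mean HR ((bpm - 60)/30),
#' SDNN (/50 ms), RMSSD (/50 ms), LF and HF log-power (log1p(ms^2)/5),
#' log LF/HF ratio, respiration (Hz, centered at 0.2), in-bed. The
#' centerings keep every channel near zero at rest, which conditions the
#' downstream network. Undefined features are encoded as 0 (the mask
#' channel marks padding, not feature missingness).
#'
#' @param t A [tachogram()].
#' @param f An `epoch_features` frame from [compute_epoch_features()].
#' @param context_epochs Non-negative integer: epochs of context per side.
#' @return A list of class `"feature_tensor"`: `x` (array
#'   `n_epochs x n_channels x samples`), `channels`, `context_epochs`.
#' @export
assemble_inputs <- function(t, f, context_epochs = 0) {
  stopifnot(inherits(t, "tachogram"), inherits(f, "epoch_features"))
  if (context_epochs < 0) stop("context_epochs must be >= 0")
  n_ep <- nrow(f)
  spe <- round(30 * t$rate_hz)                    # samples per epoch
  width <- (2 * context_epochs + 1) * spe
  channels <- c("rr_s", "mask", "mean_hr", "sdnn", "rmssd",
                "lf_power", "hf_power", "lf_hf_ratio", "resp_rate", "in_bed")
  x <- array(0, dim = c(n_ep, length(channels), width))
  total <- n_ep * spe
  rr_full <- rep(NA_real_, total)
  take <- seq_len(min(total, length(t$rr_ms)))
  rr_full[take] <- t$rr_ms[take] / 1000 - 1
  z <- function(v) ifelse(is.na(v), 0, v)
  feats <- cbind(z((f$mean_hr - 60) / 30), z(f$sdnn) / 50, z(f$rmssd) / 50,
                 log1p(z(f$lf_power)) / 5, log1p(z(f$hf_power)) / 5,
                 log1p(z(f$lf_hf_ratio)), z(f$resp_rate - 0.2),
                 as.numeric(f$in_bed))
  for (i in seq_len(n_ep)) {
    g0 <- (i - 1 - context_epochs) * spe + 1      # global sample range
    gidx <- g0:(g0 + width - 1)
    valid <- gidx >= 1 & gidx <= total & !is.na(rr_full[pmax(pmin(gidx, total), 1)])
    vals <- numeric(width)
    vals[valid] <- rr_full[gidx[valid]]
    x[i, 1, ] <- vals
    x[i, 2, ] <- as.numeric(valid)
    for (k in seq_len(ncol(feats))) x[i, 2 + k, ] <- feats[i, k]
  }
  structure(list(x = x, channels = channels, context_epochs = context_epochs),
            class = "feature_tensor")
}
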