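#' Signal-quality configuration
#'
#' Parameters of the sliding-window SNR index and the epoch/recording
#' rejection rules. Defaults are the published operating point: the ECG
#' amplitude is estimated by maximum filtering over 3-s windows, the noise
#' amplitude as sqrt(2) times the RMS of the background over 10-s windows,
#' an epoch is rejected when 50% or more of its samples fall below 5 dB,
#' and a recording is excluded when 10% or more of its epochs are rejected.
#' Both percentage boundaries are inclusive; the dB threshold is strict.
#'
#' @param signal_window_s Max-filter window (s).
#' @param noise_window_s RMS window (s).
#' @param snr_threshold_db Per-sample SNR threshold (dB, strict `<`).
#' @param epoch_reject_fraction Epoch rejection boundary (inclusive `>=`).
#' @param recording_exclude_fraction Recording exclusion boundary
#'   (inclusive `>=`).
#' @param wavelet_name Name of the built-in decomposition
#'   (`"atrous-b3"`, an a-trous B3-spline stationary wavelet transform).
#' @param signal_band_hz Two-vector: band (Hz) whose wavelet detail levels
#'   are summed into the signal component (default 5-32 Hz, the QRS energy
#'   band).
#' @param decompose Optional hook `function(samples, fs)` returning
#'   `list(signal =, background =)`; overrides the wavelet decomposition
#'   so the SNR/rejection machinery can be tested in isolation.
#' @return A list of class `"qc_config"`.
#' @export
qc_config <- function(signal_window_s = 3, noise_window_s = 10,
                      snr_threshold_db = 5, epoch_reject_fraction = 0.5,
                      recording_exclude_fraction = 0.1,
                      wavelet_name = "atrous-b3",
                      signal_band_hz = c(5, 32), decompose = NULL) {
  if (signal_window_s <= 0 || noise_window_s <= 0) {
    stop("window lengths must be positive")
  }
  for (f in c(epoch_reject_fraction, recording_exclude_fraction)) {
    if (f <= 0 || f > 1) stop("rejection fractions must lie in (0, 1]")
  }
  structure(list(signal_window_s = signal_window_s,
                 noise_window_s = noise_window_s,
                 snr_threshold_db = snr_threshold_db,
                 epoch_reject_fraction = epoch_reject_fraction,
                 recording_exclude_fraction = recording_exclude_fraction,
                 wavelet_name = wavelet_name,
                 signal_band_hz = signal_band_hz,
                 decompose = decompose),
            class = "qc_config")
}

# ---- building blocks ------------------------------------------------------

# sliding maximum, centered window w (odd), van Herk/Gil-Werman O(n);
# edges handled by reflect padding so the output has full length
.max_filter <- function(x, w) {
  n <- length(x)
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- .reflect_pad(x, h)
  np <- length(xp)
  nblocks <- ceiling(np / w)
  xpad <- c(xp, rep(-Inf, nblocks * w - np))
  m <- matrix(xpad, nrow = w)
  pref <- apply(m, 2, cummax)                       # prefix max within block
  suff <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  pref <- as.vector(pref); suff <- as.vector(suff)
  centers <- (h + 1):(h + n)                        # positions in xp
  pmax(suff[centers - h], pref[centers + h])
}

# sliding RMS, centered window w, reflect padding, O(n) via cumsum
.rms_filter <- function(x, w) {
  n <- length(x)
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- .reflect_pad(x, h)^2
  cs <- cumsum(xp)
  s <- cs[(w):length(xp)] - c(0, cs[seq_len(length(xp) - w)])
  sqrt(s / w)
}

.reflect_pad <- function(x, h) {
  n <- length(x)
  if (h == 0) return(x)
  if (h >= n) {                      # degenerate: tile reflection
    reps <- ceiling(h / n)
    left <- rep(rev(x), reps)[1:h]
    right <- rep(rev(x), reps)[1:h]
    return(c(rev(left), x, right))
  }
  c(x[(h + 1):2], x, x[(n - 1):(n - h)])
}

#' A-trous B3-spline stationary wavelet decomposition
#'
#' Additive, shift-invariant wavelet decomposition (the "starlet"
#' transform): repeated smoothing with the upsampled B3-spline kernel
#' `(1,4,6,4,1)/16` yields detail layers `d_j = a_{j-1} - a_j` whose sum
#' plus the final approximation reconstructs the input exactly. Detail
#' level j carries energy roughly in the dyadic band
#' `[fs/2^(j+1), fs/2^j]` Hz. The signal component is the sum of all
#' detail levels whose band intersects `band`; the background is the
#' residual `x - signal`. The transform is linear, so the SNR in dB is
#' invariant to rescaling the input.
#'
#' @param x Numeric samples.
#' @param fs Sampling rate (Hz).
#' @param band Two-vector band (Hz) defining the signal levels.
#' @return `list(signal =, background =, levels = selected level indices)`.
#' @export
atrous_decompose <- function(x, fs, band = c(5, 32)) {
  h0 <- c(1, 4, 6, 4, 1) / 16
  # keep smoothing until the remaining approximation is fully below band[1]
  n_lev <- max(1L, ceiling(log2(fs / band[1])) - 1L)
  a <- x
  sig <- numeric(length(x))
  selected <- integer(0)
  for (j in seq_len(n_lev)) {
    hj <- rep(0, (length(h0) - 1) * 2^(j - 1) + 1)
    hj[seq(1, length(hj), by = 2^(j - 1))] <- h0
    half <- (length(hj) - 1L) %/% 2L
    ap <- .reflect_pad(a, half)
    sm <- stats::filter(ap, hj, sides = 2)
    sm <- as.numeric(sm[(half + 1):(half + length(a))])
    d <- a - sm
    lo <- fs / 2^(j + 1); hi <- fs / 2^j
    if (hi > band[1] && lo < band[2]) {
      sig <- sig + d
      selected <- c(selected, j)
    }
    a <- sm
  }
  list(signal = sig, background = x - sig, levels = selected)
}

#' Per-sample ECG signal-to-noise ratio
#'
#' Separates the record into signal and background components (wavelet
#' decomposition by default, or the config's injected hook), then slides
#' two windows one sample at a time: `a_signal[i]` is the maximum of
#' `|signal|` over the 3-s window centered at i; `a_noise[i]` is
#' `sqrt(2)` times the RMS of the background over the 10-s window centered
#' at i; and `snr_db[i] = 20 * log10(a_signal[i] / a_noise[i])`, clipped
#' to \[-40, +80\] dB with the noise amplitude floored away from zero.
#'
#' @param e An [ecg_record()], at least `noise_window_s` long.
#' @param cfg A [qc_config()].
#' @return A list of class `"snr_series"`: `snr_db`, `a_signal`,
#'   `a_noise`, `fs` (all per-sample, same length as the record).
#' @export
compute_snr <- function(e, cfg = qc_config()) {
  stopifnot(inherits(e, "ecg_record"))
  if (ecg_duration(e) < cfg$noise_window_s) {
    stop("record shorter than the noise window (",
         cfg$noise_window_s, " s)")
  }
  dec <- if (is.null(cfg$decompose)) {
    atrous_decompose(e$samples, e$fs, cfg$signal_band_hz)
  } else {
    cfg$decompose(e$samples, e$fs)
  }
  w_sig <- max(1L, round(cfg$signal_window_s * e$fs))
  w_noise <- max(1L, round(cfg$noise_window_s * e$fs))
  a_signal <- .max_filter(abs(dec$signal), w_sig)
  a_noise <- sqrt(2) * .rms_filter(dec$background, w_noise)
  floor_amp <- .Machine$double.eps * max(a_signal, 1)
  snr_db <- 20 * log10(a_signal / pmax(a_noise, floor_amp))
  snr_db <- pmax(pmin(snr_db, 80), -40)
  structure(list(snr_db = snr_db, a_signal = a_signal, a_noise = a_noise,
                 fs = e$fs),
            class = "snr_series")
}

#' Classify 30-s epochs as accepted or rejected from the SNR series
#'
#' An epoch is rejected when the fraction of its samples with SNR strictly
#' below the threshold is greater than or equal to
#' `epoch_reject_fraction` (boundary inclusive).
#'
#' @param s An `snr_series` from [compute_snr()].
#' @param n_epochs Number of 30-s epochs; defaults to all full epochs
#'   covered by the series.
#' @param cfg A [qc_config()].
#' @return A list of class `"quality_report"` with `epoch_rejected`
#'   (logical per epoch), `fraction_rejected`, `recording_excluded`
#'   (`NA` until [assess_recording()]), and the config.
#' @export
classify_epochs <- function(s, n_epochs = NULL, cfg = qc_config()) {
  stopifnot(inherits(s, "snr_series"))
  spe <- round(30 * s$fs)
  if (is.null(n_epochs)) n_epochs <- floor(length(s$snr_db) / spe)
  if (n_epochs < 1) stop("epoch grid is empty")
  if (n_epochs * spe > length(s$snr_db)) {
    stop("epoch grid not covered by the SNR series")
  }
  below <- s$snr_db < cfg$snr_threshold_db
  frac_below <- vapply(seq_len(n_epochs), function(i) {
    mean(below[((i - 1) * spe + 1):(i * spe)])
  }, 0)
  rejected <- frac_below >= cfg$epoch_reject_fraction
  structure(list(epoch_rejected = rejected,
                 fraction_rejected = mean(rejected),
                 recording_excluded = NA,
                 config = cfg),
            class = "quality_report")
}

#' Apply the recording-level exclusion rule
#'
#' A recording is excluded when the fraction of rejected epochs is greater
#' than or equal to `recording_exclude_fraction` (boundary inclusive).
#' Retained recordings keep every epoch for downstream scoring, including
#' the rejected ones — rejection only feeds the exclusion decision.
#'
#' @param q A `quality_report` from [classify_epochs()].
#' @param cfg A [qc_config()]; defaults to the report's own config.
#' @return The completed `quality_report` with `recording_excluded` set.
#' @export
assess_recording <- function(q, cfg = NULL) {
  stopifnot(inherits(q, "quality_report"))
  if (is.null(cfg)) cfg <- q$config
  q$fraction_rejected <- mean(q$epoch_rejected)
  q$recording_excluded <-
    q$fraction_rejected >= cfg$recording_exclude_fraction
  q$config <- cfg
  q
}

#' One-shot quality control for a record
#'
#' Convenience wrapper: [compute_snr()], [classify_epochs()],
#' [assess_recording()].
#'
#' @param e An [ecg_record()].
#' @param cfg A [qc_config()].
#' @return A completed `quality_report` with the `snr` series attached.
#' @export
qc_record <- function(e, cfg = qc_config()) {
  s <- compute_snr(e, cfg)
  q <- assess_recording(classify_epochs(s, cfg = cfg), cfg)
  q$snr <- s
  q
}

#' Write a quality report as JSON
#'
#' @param q A `quality_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(q, path) {
  stopifnot(inherits(q, "quality_report"))
  cfg <- q$config
  out <- list(
    epoch_rejected = q$epoch_rejected,
    fraction_rejected = q$fraction_rejected,
    recording_excluded = q$recording_excluded,
    config = list(
      signal_window_s = cfg$signal_window_s,
      noise_window_s = cfg$noise_window_s,
      snr_threshold_db = cfg$snr_threshold_db,
      epoch_reject_fraction = cfg$epoch_reject_fraction,
      recording_exclude_fraction = cfg$recording_exclude_fraction,
      wavelet_name = cfg$wavelet_name,
      signal_band_hz = cfg$signal_band_hz
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a quality report written by [write_qc_report()]
#'
#' @param path JSON path.
#' @return A `quality_report` (without the SNR series).
#' @export
read_qc_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(qc_config, j$config[setdiff(names(j$config), "wavelet_name")])
  cfg$wavelet_name <- j$config$wavelet_name
  structure(list(epoch_rejected = as.logical(j$epoch_rejected),
                 fraction_rejected = j$fraction_rejected,
                 recording_excluded = j$recording_excluded,
                 config = cfg),
            class = "quality_report")
}
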