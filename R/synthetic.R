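#' Markov hypnogram model configuration
#'
#' Defines the first-order Markov chain over \{W, N1, N2, N3, R\} used to
#' simulate reference hypnograms. The default transition matrix encodes
#' typical overnight dynamics at the 30-s epoch scale: sticky N2/N3/REM
#' runs, brief N1, and occasional awakenings.
#'
#' @param transition 5x5 row-stochastic matrix, rows/cols ordered
#'   (W, N1, N2, N3, R).
#' @param initial Probability 5-vector for the first epoch.
#' @param n_epochs Number of 30-s epochs to generate.
#' @param seed Integer seed.
#' @return A list of class `"hypnogram_model_config"`.
#' @export
hypnogram_model_config <- function(transition = NULL, initial = NULL,
                                   n_epochs = 960, seed = 1) {
  if (is.null(transition)) {
    transition <- matrix(c(
      0.90, 0.08, 0.02, 0.00, 0.00,   # W
      0.05, 0.70, 0.24, 0.00, 0.01,   # N1
      0.02, 0.03, 0.88, 0.05, 0.02,   # N2
      0.01, 0.01, 0.08, 0.90, 0.00,   # N3
      0.02, 0.03, 0.02, 0.00, 0.93    # R
    ), nrow = 5, byrow = TRUE, dimnames = list(STAGES_AASM5, STAGES_AASM5))
  }
  if (is.null(initial)) initial <- c(1, 0, 0, 0, 0)
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(5, 5))) stop("transition must be 5x5")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must be non-negative and sum to 1 (within 1e-9)")
  }
  if (length(initial) != 5 || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop("initial must be a probability 5-vector")
  }
  if (n_epochs < 1) stop("n_epochs must be positive")
  structure(list(transition = transition, initial = initial,
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "hypnogram_model_config")
}

#' Simulate a hypnogram from a Markov chain
#'
#' Deterministic given the config's seed.
#'
#' @param cfg A [hypnogram_model_config()].
#' @param start_time Start time (UTC seconds) of epoch 0.
#' @param subject_id Subject identifier.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(cfg, start_time = 0, subject_id = "S1") {
  stopifnot(inherits(cfg, "hypnogram_model_config"))
  set.seed(.as_seed(cfg$seed))
  states <- integer(cfg$n_epochs)
  states[1] <- sample.int(5, 1L, prob = cfg$initial)
  if (cfg$n_epochs > 1) {
    for (i in 2:cfg$n_epochs) {
      states[i] <- sample.int(5, 1L, prob = cfg$transition[states[i - 1], ])
    }
  }
  hypnogram(STAGES_AASM5[states], start_time = start_time,
            subject_id = subject_id)
}

#' Stationary distribution of a stage transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to a probability vector. Used as the analytic oracle for long-run stage
#' frequencies.
#'
#' @param transition Row-stochastic matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(transition))
}

#' Stage-conditioned RR dynamics configuration
#'
#' Per-stage RR baseline and variability used to synthesize tachograms.
#' RR(t) is the sum of a stage baseline, a low-frequency (~0.1 Hz)
#' oscillation, a high-frequency oscillation at the stage respiratory rate
#' (this doubles as the respiration ground truth), and white jitter scaled
#' so the total variance matches sdnn^2. The REM/NREM contrast follows the
#' established autonomic pattern: elevated LF power and reduced HF power in
#' REM relative to deep sleep.
#'
#' The `"easy"` regime widens the between-stage HR separation and shrinks
#' the jitter; it is the benign end of the generator's dial, used when a
#' study needs stages that are clearly recoverable from HR alone.
#'
#' @param regime `"default"` (literature-plausible overnight values) or
#'   `"easy"` (strong stage separation).
#' @param stages Optionally, a data.frame with columns
#'   `stage, mean_rr, sdnn, lf_power, hf_power, resp_rate` overriding the
#'   regime table (rows for W, N1, N2, N3, R).
#' @param transition_smoothing_s Cross-fade length at stage boundaries
#'   (seconds).
#' @return A list of class `"stage_dynamics_config"`.
#' @export
stage_dynamics_config <- function(regime = c("default", "easy"),
                                  stages = NULL,
                                  transition_smoothing_s = 30) {
  regime <- match.arg(regime)
  if (is.null(stages)) {
    stages <- if (regime == "default") {
      data.frame(
        stage = STAGES_AASM5,
        mean_rr = c(850, 950, 1000, 1050, 900),
        sdnn = c(60, 50, 45, 30, 55),
        lf_power = c(900, 700, 500, 150, 1200),
        hf_power = c(300, 350, 500, 600, 250),
        resp_rate = c(0.25, 0.22, 0.20, 0.18, 0.24)
      )
    } else {
      data.frame(
        stage = STAGES_AASM5,
        mean_rr = c(750, 950, 1000, 1150, 880),
        sdnn = c(25, 22, 20, 15, 22),
        lf_power = c(220, 130, 80, 30, 350),
        hf_power = c(80, 120, 200, 180, 60),
        resp_rate = c(0.25, 0.22, 0.20, 0.18, 0.24)
      )
    }
  }
  need <- c("stage", "mean_rr", "sdnn", "lf_power", "hf_power", "resp_rate")
  stopifnot(all(need %in% names(stages)),
            setequal(stages$stage, STAGES_AASM5))
  if (any(stages$mean_rr < 300 | stages$mean_rr > 1500)) {
    stop("mean_rr must lie in [300, 1500] ms")
  }
  if (any(stages$lf_power < 0) || any(stages$hf_power < 0)) {
    stop("band powers must be >= 0")
  }
  if (any(stages$resp_rate < 0.1 | stages$resp_rate > 0.5)) {
    stop("resp_rate must lie in [0.1, 0.5] Hz")
  }
  rownames(stages) <- stages$stage
  structure(list(stages = stages,
                 transition_smoothing_s = transition_smoothing_s),
            class = "stage_dynamics_config")
}

# Piecewise-constant per-stage parameter profile on a fine time grid with
# linear cross-fades over transition_smoothing_s at stage boundaries.
.stage_profile <- function(h, dyn, param, t) {
  vals <- dyn$stages[h$labels, param]
  onset <- epoch_onsets(h) - h$start_time
  step_val <- vals[pmin(findInterval(t, onset), length(vals))]
  sm <- dyn$transition_smoothing_s
  if (sm <= 0) return(step_val)
  # moving-average the step profile over sm seconds => linear cross-fade
  dt <- t[2] - t[1]
  w <- max(1L, round(sm / dt))
  if (w %% 2 == 0) w <- w + 1L
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(step_val[1], pad), step_val, rep(step_val[length(step_val)], pad))
  cs <- cumsum(xp)
  (cs[(w):length(xp)] - c(0, cs[seq_len(length(xp) - w)])) / w
}

#' Simulate an R-peak series conditioned on a hypnogram
#'
#' Realizes stage-dependent RR dynamics: within each stage run, RR
#' fluctuates around the configured stage mean with an LF oscillation at
#' 0.095-0.105 Hz, an HF oscillation at the stage respiratory rate, and
#' white jitter topping the variance up to sdnn^2. Oscillation amplitudes
#' are `sqrt(2 * power)` so band powers match the configured ms^2 values.
#' Stage boundaries are blended by a linear cross-fade. Beat times are
#' obtained by integrating the instantaneous RR.
#'
#' @param h A [hypnogram()].
#' @param dyn A [stage_dynamics_config()].
#' @param seed Integer seed.
#' @return An `rpeak_series` (see [rpeak_series()]), beat times in seconds
#'   from the start of the hypnogram.
#' @export
simulate_rr_series <- function(h, dyn = stage_dynamics_config(), seed = 1) {
  stopifnot(inherits(h, "hypnogram"))
  if (length(h$labels) == 0L) stop("empty hypnogram")
  set.seed(.as_seed(seed))
  dur <- 30 * length(h$labels)
  grid_dt <- 0.25
  t <- seq(0, dur, by = grid_dt)
  mean_rr <- .stage_profile(h, dyn, "mean_rr", t)
  lf_p <- .stage_profile(h, dyn, "lf_power", t)
  hf_p <- .stage_profile(h, dyn, "hf_power", t)
  sdnn <- .stage_profile(h, dyn, "sdnn", t)
  resp <- .stage_profile(h, dyn, "resp_rate", t)

  f_lf <- stats::runif(1, 0.095, 0.105)
  ph_lf <- stats::runif(1, 0, 2 * pi)
  ph_hf <- stats::runif(1, 0, 2 * pi)
  # HF phase advances at the (time-varying) respiratory rate
  hf_phase <- ph_hf + 2 * pi * cumsum(resp) * grid_dt
  rr_t <- mean_rr +
    sqrt(2 * lf_p) * sin(2 * pi * f_lf * t + ph_lf) +
    sqrt(2 * hf_p) * sin(hf_phase)
  jitter_sd <- sqrt(pmax(0, sdnn^2 - lf_p - hf_p))

  # integrate instantaneous RR to beat times; jitter drawn per beat
  times <- numeric(ceiling(dur / 0.3) + 2L)
  tk <- 0.5
  k <- 0L
  n_t <- length(t)
  while (tk < dur - 0.5) {
    k <- k + 1L
    times[k] <- tk
    i <- min(n_t, max(1L, 1L + as.integer(round(tk / grid_dt))))
    rr_ms <- rr_t[i] +
      if (jitter_sd[i] > 0) stats::rnorm(1) * jitter_sd[i] else 0
    tk <- tk + max(0.3, rr_ms / 1000)
  }
  if (k == 0L) stop("hypnogram too short to place beats")
  rpeak_series(times[seq_len(k)], quality = rep("ok", k), source_fs = NA_real_)
}

#' ECG waveform synthesis configuration
#'
#' @param fs Sampling rate (Hz), >= 100.
#' @param qrs_amplitude QRS peak amplitude (mV).
#' @param qrs_width_ms QRS template width in ms (40-160).
#' @param baseline_wander_amp Amplitude (mV) of a 0.25 Hz baseline drift.
#' @param noise_segments List of `c(start_s, end_s, noise_sd_mv)` triplets;
#'   Gaussian noise of the given SD is added inside each segment.
#' @param template `"ricker"` (Mexican hat, zero-mean; default) or
#'   `"gaussian"`.
#' @return A list of class `"ecg_synth_config"`.
#' @export
ecg_synth_config <- function(fs = 256, qrs_amplitude = 1.0, qrs_width_ms = 100,
                             baseline_wander_amp = 0, noise_segments = list(),
                             template = c("ricker", "gaussian")) {
  template <- match.arg(template)
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (qrs_width_ms < 40 || qrs_width_ms > 160) {
    stop("qrs_width_ms must lie in [40, 160]")
  }
  if (fs * qrs_width_ms / 1000 < 4) {
    stop("fs too low to represent the QRS template (need >= 4 samples per pulse)")
  }
  structure(list(fs = fs, qrs_amplitude = qrs_amplitude,
                 qrs_width_ms = qrs_width_ms,
                 baseline_wander_amp = baseline_wander_amp,
                 noise_segments = noise_segments, template = template),
            class = "ecg_synth_config")
}

#' Synthesize an ECG waveform from beat times
#'
#' Places one QRS-like template (Ricker or Gaussian pulse of the configured
#' width) at each beat time on a uniform sample grid, then adds baseline
#' wander and segment-local Gaussian noise. Morphological realism is
#' deliberately out of scope: the downstream pipeline uses HR only, so the
#' waveform only needs a sharp, band-limited deflection per beat.
#'
#' @param r An [rpeak_series()] with beat times in seconds.
#' @param cfg An [ecg_synth_config()].
#' @param duration_s Record duration; defaults to last beat + 1 s.
#' @param seed Seed for the noise segments.
#' @return An [ecg_record()].
#' @export
synthesize_ecg <- function(r, cfg = ecg_synth_config(), duration_s = NULL,
                           seed = 1) {
  stopifnot(inherits(r, "rpeak_series"))
  if (is.null(duration_s)) duration_s <- max(r$times_s) + 1
  if (any(r$times_s < 0 | r$times_s > duration_s)) {
    stop("beat times must lie within the requested duration")
  }
  fs <- cfg$fs
  n <- ceiling(duration_s * fs)
  x <- numeric(n)
  sigma <- cfg$qrs_width_ms / 1000 / 5      # pulse support ~ +/- 2.5 sigma
  half <- ceiling(4 * sigma * fs)
  for (tb in r$times_s) {
    c_idx <- round(tb * fs) + 1L
    lo <- max(1L, c_idx - half); hi <- min(n, c_idx + half)
    tt <- ((lo:hi) - 1L) / fs - tb
    u <- (tt / sigma)^2
    pulse <- if (cfg$template == "ricker") {
      cfg$qrs_amplitude * (1 - u) * exp(-u / 2)
    } else {
      cfg$qrs_amplitude * exp(-u / 2)
    }
    x[lo:hi] <- x[lo:hi] + pulse
  }
  tt <- (seq_len(n) - 1L) / fs
  if (cfg$baseline_wander_amp != 0) {
    x <- x + cfg$baseline_wander_amp * sin(2 * pi * 0.25 * tt)
  }
  if (length(cfg$noise_segments)) {
    set.seed(.as_seed(seed))
    for (seg in cfg$noise_segments) {
      idx <- which(tt >= seg[1] & tt < seg[2])
      if (length(idx)) x[idx] <- x[idx] + stats::rnorm(length(idx)) * seg[3]
    }
  }
  ecg_record(x, fs = fs, start_time = 0, channel_label = "ECG synth")
}

#' Subject metadata
#'
#' @param subject_id Identifier.
#' @param age_group One of `"<=40"`, `"40-60"`, `">60"`.
#' @param ahi_group One of `"none/minimal"`, `"mild"`, `"severe"`.
#' @param sex `"M"` or `"F"`.
#' @return A one-row data.frame.
#' @export
subject_meta <- function(subject_id, age_group, ahi_group, sex) {
  age_group <- match.arg(age_group, AGE_GROUPS)
  ahi_group <- match.arg(ahi_group, AHI_GROUPS)
  sex <- match.arg(sex, SEX_GROUPS)
  data.frame(subject_id = subject_id, age_group = age_group,
             ahi_group = ahi_group, sex = sex, stringsAsFactors = FALSE)
}

#' @rdname subject_meta
#' @export
AGE_GROUPS <- c("<=40", "40-60", ">60")

#' @rdname subject_meta
#' @export
AHI_GROUPS <- c("none/minimal", "mild", "severe")

#' @rdname subject_meta
#' @export
SEX_GROUPS <- c("F", "M")

#' Simulate a cohort with known ground truth
#'
#' Generates `n_subjects` subjects, each with a Markov hypnogram, balanced
#' round-robin metadata over the age/AHI/sex strata, optionally an RR
#' series or full ECG, and optionally a degraded predicted hypnogram with
#' plantable group effects for testing the covariate-regression stage.
#'
#' Predicted labels are built by flipping each epoch of the (4-level
#' collapsed) reference to a random wrong class with probability
#' `1 - base_accuracy`, plus the planted extra flip probability for
#' subjects in the affected group. The expected accuracy of an affected
#' subject is therefore lower by exactly the planted amount.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_epochs Epochs per subject.
#' @param dynamics A [stage_dynamics_config()]; used when `signal != "none"`.
#' @param signal `"none"`, `"rpeaks"` or `"ecg"` — how much raw signal to
#'   synthesize per subject.
#' @param base_accuracy Expected epoch accuracy of the simulated
#'   predictions in the unaffected groups; `NULL` disables predictions.
#' @param planted_effects Named numeric vector of accuracy decrements by
#'   group level, e.g. `c(">60" = 0.05)`. Names must be levels of
#'   age/AHI/sex groups.
#' @param ecg_cfg An [ecg_synth_config()] when `signal == "ecg"`.
#' @param seed Integer seed.
#' @return A list of class `"cohort"`: `$subjects` (list with `hypnogram`,
#'   `meta`, optional `rpeaks`, `ecg`, `pred4`) and `$meta` (row-bound
#'   metadata).
#' @export
simulate_cohort <- function(n_subjects, n_epochs = 960,
                            dynamics = stage_dynamics_config(),
                            signal = c("none", "rpeaks", "ecg"),
                            base_accuracy = NULL, planted_effects = NULL,
                            ecg_cfg = ecg_synth_config(), seed = 1) {
  signal <- match.arg(signal)
  if (n_subjects < 2) stop("need at least 2 subjects")
  groups <- list(age_group = AGE_GROUPS, ahi_group = AHI_GROUPS,
                 sex = SEX_GROUPS)
  if (!is.null(planted_effects)) {
    lv <- unlist(groups, use.names = FALSE)
    bad <- setdiff(names(planted_effects), lv)
    if (length(bad)) stop("unknown planted-effect level(s): ",
                          paste(bad, collapse = ", "))
    affected_fac <- vapply(names(planted_effects), function(nm) {
      names(groups)[vapply(groups, function(g) nm %in% g, TRUE)][1]
    }, "")
    # require >= 2 subjects per level of each affected factor
    for (fac in unique(affected_fac)) {
      if (n_subjects < 2 * length(groups[[fac]])) {
        stop("planted effects need >= 2 subjects per stratum of '", fac, "'")
      }
    }
  }
  subjects <- vector("list", n_subjects)
  meta <- NULL
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    m <- subject_meta(
      sid,
      AGE_GROUPS[1 + (s - 1) %% 3],
      AHI_GROUPS[1 + ((s - 1) %/% 3) %% 3],
      SEX_GROUPS[1 + (s - 1) %% 2]
    )
    hcfg <- hypnogram_model_config(n_epochs = n_epochs,
                                   seed = seed * 10007L + s)
    h <- simulate_hypnogram(hcfg, subject_id = sid)
    sub <- list(hypnogram = h, meta = m)
    if (signal %in% c("rpeaks", "ecg")) {
      sub$rpeaks <- simulate_rr_series(h, dynamics, seed = seed * 20011L + s)
      if (signal == "ecg") {
        sub$ecg <- synthesize_ecg(sub$rpeaks, ecg_cfg,
                                  duration_s = 30 * n_epochs,
                                  seed = seed * 30011L + s)
      }
    }
    if (!is.null(base_accuracy)) {
      flip_p <- 1 - base_accuracy
      if (!is.null(planted_effects)) {
        for (nm in names(planted_effects)) {
          if (nm %in% unlist(m[names(groups)])) {
            flip_p <- flip_p + planted_effects[[nm]]
          }
        }
      }
      sub$pred4 <- .flip_labels(collapse_stages(h$labels, "aasm5", 4),
                                flip_p, seed = seed * 40009L + s)
    }
    subjects[[s]] <- sub
    meta <- rbind(meta, m)
  }
  structure(list(subjects = subjects, meta = meta), class = "cohort")
}

# flip each label with probability p to a uniformly random *different* class
.flip_labels <- function(labels4, p, seed) {
  set.seed(.as_seed(seed))
  n <- length(labels4)
  flip <- stats::runif(n) < p
  out <- labels4
  for (i in which(flip)) {
    alt <- setdiff(STAGES_L4, labels4[i])
    out[i] <- alt[sample.int(3L, 1L)]
  }
  out
}

# fold any numeric seed into the 32-bit range set.seed accepts
.as_seed <- function(seed) as.integer(abs(seed) %% 2147483646 + 1)
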