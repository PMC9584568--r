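#' A device recording window for alignment
#'
#' @param device_id Device identifier.
#' @param labels Stage labels (5-class AASM or 4-level), one per 30-s
#'   epoch. `NA` entries mark interior dropouts.
#' @param start_time Absolute start time of epoch 0 (UTC seconds).
#' @param lights_off_time Lights-off (sleep-opportunity start) time; must
#'   be `>= start_time`. Defaults to `start_time` when no diary or
#'   position-derived value is available.
#' @return A list of class `"recording_window"`.
#' @export
recording_window <- function(device_id, labels, start_time,
                             lights_off_time = start_time) {
  if (lights_off_time < start_time) {
    stop("lights_off_time must be >= start_time")
  }
  structure(list(device_id = device_id, labels = as.character(labels),
                 start_time = as.numeric(start_time),
                 lights_off_time = as.numeric(lights_off_time)),
            class = "recording_window")
}

#' Align two simultaneously recorded devices onto one epoch grid
#'
#' The common grid starts at the earlier of the two lights-off times and
#' uses 30-s epochs. Each device's label sequence is placed on the grid
#' at its own offset; epochs a device does not cover — leading, trailing,
#' or interior dropouts — are filled with W ("awake time") and flagged as
#' padded. Sub-epoch offsets are snapped to the nearest epoch boundary
#' and the residual (always < 15 s) is reported.
#'
#' @param a,b [recording_window()] objects on a common clock.
#' @return A list of class `"aligned_pair"`: `grid_start`, `n_epochs`,
#'   `labels_a`, `labels_b` (equal lengths), `padded_a`, `padded_b`
#'   (logical), `residual_a_s`, `residual_b_s` (sub-epoch snap
#'   residuals).
#' @export
align_pair <- function(a, b) {
  stopifnot(inherits(a, "recording_window"), inherits(b, "recording_window"))
  a_end <- a$start_time + 30 * length(a$labels)
  b_end <- b$start_time + 30 * length(b$labels)
  if (min(a_end, b_end) <= max(a$start_time, b$start_time)) {
    stop("recordings do not overlap in time")
  }
  grid_start <- min(a$lights_off_time, b$lights_off_time)
  grid_end <- max(a_end, b_end)
  n_epochs <- ceiling((grid_end - grid_start) / 30)
  place <- function(w) {
    off_raw <- (w$start_time - grid_start) / 30
    off <- round(off_raw)                       # snap to epoch boundary
    residual <- (off_raw - off) * 30
    lab <- rep("W", n_epochs)
    padded <- rep(TRUE, n_epochs)
    src <- seq_along(w$labels)
    dst <- src + off
    keep <- dst >= 1 & dst <= n_epochs
    lab[dst[keep]] <- w$labels[src[keep]]
    padded[dst[keep]] <- FALSE
    # interior dropouts: NA labels are W-filled and flagged padded
    drop <- dst[keep][is.na(w$labels[src[keep]])]
    if (length(drop)) {
      lab[drop] <- "W"
      padded[drop] <- TRUE
    }
    list(labels = lab, padded = padded, residual = residual)
  }
  pa <- place(a); pb <- place(b)
  structure(list(grid_start = grid_start, n_epochs = n_epochs,
                 labels_a = pa$labels, labels_b = pb$labels,
                 padded_a = pa$padded, padded_b = pb$padded,
                 residual_a_s = pa$residual, residual_b_s = pb$residual,
                 device_a = a$device_id, device_b = b$device_id),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf(
    "<aligned_pair> %s vs %s: %d epochs from t=%g s (%d / %d padded)\n",
    x$device_a, x$device_b, x$n_epochs, x$grid_start,
    sum(x$padded_a), sum(x$padded_b)))
  invisible(x)
}

#' Write an aligned pair as CSV
#'
#' Columns: `epoch_index,onset_s,label_a,padded_a,label_b,padded_b`.
#'
#' @param ap An `aligned_pair`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_aligned_pair <- function(ap, path) {
  stopifnot(inherits(ap, "aligned_pair"))
  df <- data.frame(epoch_index = seq_len(ap$n_epochs) - 1L,
                   onset_s = ap$grid_start + 30 * (seq_len(ap$n_epochs) - 1L),
                   label_a = ap$labels_a, padded_a = ap$padded_a,
                   label_b = ap$labels_b, padded_b = ap$padded_b)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
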