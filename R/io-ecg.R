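#' Construct an ECG record
#'
#' The entry point of the pipeline: a single channel of ECG samples in
#' millivolt, with its sampling rate and absolute start time.
#'
#' @param samples Numeric vector of samples (mV), non-empty.
#' @param fs Sampling rate in Hz, > 0.
#' @param start_time Absolute start time (UTC seconds). Default 0.
#' @param channel_label Channel name.
#' @return An object of class `"ecg_record"`.
#' @export
ecg_record <- function(samples, fs, start_time = 0, channel_label = "ECG") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("ECG record must contain samples")
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop("sampling rate must be > 0")
  structure(
    list(samples = samples, fs = fs, start_time = as.numeric(start_time),
         channel_label = as.character(channel_label)),
    class = "ecg_record"
  )
}

#' Duration of an ECG record in seconds
#' @param e An [ecg_record()].
#' @return Duration `length(samples) / fs` in seconds.
#' @export
ecg_duration <- function(e) {
  stopifnot(inherits(e, "ecg_record"))
  length(e$samples) / e$fs
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> '%s': %d samples @ %g Hz (%.1f s), start %g s\n",
              x$channel_label, length(x$samples), x$fs, ecg_duration(x),
              x$start_time))
  invisible(x)
}

#' Read a single ECG channel from a WFDB or EDF file
#'
#' Dispatches on `format`. For WFDB, `path` is the `.hea` header (or the
#' record name without extension); the signal file may be a `.dat` or the
#' byte-offset `.mat` variant used by some PhysioNet distributions, as long
#' as the header declares format 16. For EDF, `path` is the `.edf` file.
#' Units and sampling rate are always taken from the header, never assumed.
#'
#' @param path File path.
#' @param format `"wfdb"` or `"edf"`.
#' @param channel Channel label (character, matched case-insensitively) or
#'   1-based index.
#' @return An [ecg_record()] with samples in mV.
#' @export
read_ecg <- function(path, format = c("wfdb", "edf"), channel = "ECG") {
  format <- match.arg(format)
  switch(format,
    wfdb = read_wfdb(path, channel = channel),
    edf = read_edf(path, channel = channel)
  )
}

# scale a physical channel to mV given the header's physical dimension
.to_mv <- function(x, unit) {
  u <- trimws(unit)
  key <- tolower(u)
  if (key %in% c("mv", "millivolt", "millivolts")) return(x)
  if (key %in% c("uv", "µv", "microvolt", "microvolts")) return(x / 1000)
  if (key %in% c("v", "volt", "volts")) return(x * 1000)
  if (nzchar(u)) {
    warning("unrecognized physical unit '", u, "'; passing samples through")
  }
  x
}

#' Read a WFDB record header and one signal channel
#'
#' Minimal WFDB support: header (`.hea`) plus a format-16 signal file
#' (16-bit little-endian two's complement, channels interleaved). Formats
#' declared as `16+N` (byte offset N, the convention used by `.mat`-wrapped
#' distributions) are honoured by skipping N bytes.
#'
#' @param path Path to the `.hea` file or the record name.
#' @param channel Channel description or label (case-insensitive) or index.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(path, channel = 1) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("corrupt WFDB header (need record + signal lines): ", hea)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) stop("corrupt WFDB record line in ", hea)
  nsig <- as.integer(rec[2])
  fs <- as.numeric(sub("/.*$", "", rec[3]))  # strip counter frequency if any
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  if (!is.finite(fs) || fs <= 0 || !is.finite(nsig) || nsig < 1) {
    stop("corrupt WFDB header fields in ", hea)
  }
  sig <- lapply(lines[2:(1 + nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  fname <- vapply(sig, `[`, "", 1)
  fmt_field <- vapply(sig, `[`, "", 2)
  fmt <- sub("\\+.*$", "", fmt_field)
  offset <- ifelse(grepl("\\+", fmt_field),
                   as.numeric(sub("^.*\\+", "", fmt_field)), 0)
  gain_field <- vapply(sig, function(s) if (length(s) >= 3) s[3] else "200", "")
  units <- ifelse(grepl("/", gain_field), sub("^[^/]*/", "", gain_field), "mV")
  gain_num <- sub("/.*$", "", gain_field)
  has_baseline <- grepl("\\(", gain_num)
  baseline <- ifelse(has_baseline,
                     as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gain_num)), 0)
  gain <- as.numeric(sub("\\(.*$", "", gain_num))
  gain[!is.finite(gain) | gain == 0] <- 200
  # adc zero (field 5) is the baseline unless one is given in parentheses
  adc_zero <- vapply(sig, function(s) {
    if (length(s) >= 5) suppressWarnings(as.numeric(s[5])) else 0
  }, 0)
  adc_zero[!is.finite(adc_zero)] <- 0
  baseline <- ifelse(has_baseline, baseline, adc_zero)
  desc <- vapply(sig, function(s) {
    if (length(s) >= 9) paste(s[9:length(s)], collapse = " ") else ""
  }, "")

  idx <- .resolve_channel(channel, desc, fallback_labels = fname)
  if (!all(fmt %in% "16")) {
    stop("unsupported WFDB signal format '", fmt[which(fmt != "16")[1]],
         "' (only format 16 is supported)")
  }
  datf <- file.path(dirname(hea), fname[idx])
  if (!file.exists(datf)) stop("WFDB signal file not found: ", datf)
  con <- file(datf, "rb")
  on.exit(close(con))
  if (offset[idx] > 0) readBin(con, "raw", n = offset[idx])
  total <- file.size(datf) - offset[idx]
  raw16 <- readBin(con, "integer", n = floor(total / 2), size = 2,
                   signed = TRUE, endian = "little")
  if (length(raw16) < nsig) stop("corrupt WFDB signal file: ", datf)
  usable <- (length(raw16) %/% nsig) * nsig
  mat <- matrix(raw16[seq_len(usable)], nrow = nsig)
  x <- (mat[idx, ] - baseline[idx]) / gain[idx]
  if (is.finite(nsamp) && nsamp > 0 && nsamp <= length(x)) x <- x[seq_len(nsamp)]
  x <- .to_mv(x, units[idx])
  lbl <- if (nzchar(desc[idx])) desc[idx] else paste0("ch", idx)
  ecg_record(x, fs = fs, start_time = 0, channel_label = lbl)
}

#' Read one channel of an EDF/EDF+ file
#'
#' Parses the fixed-format EDF header, converts digital values to physical
#' units via the per-signal calibration fields, and rescales to mV using
#' the physical-dimension field (pass-through with a warning when the unit
#' is unrecognized). Start time is taken from the header's date/time fields
#' (interpreted as UTC).
#'
#' @param path Path to the `.edf` file.
#' @param channel Channel label (case-insensitive) or 1-based index.
#' @return An [ecg_record()].
#' @export
read_edf <- function(path, channel = 1) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n = n))
  version <- rd(8)
  rd(80); rd(80)                      # patient / recording id
  date_s <- trimws(rd(8)); time_s <- trimws(rd(8))
  header_bytes <- suppressWarnings(as.integer(trimws(rd(8))))
  rd(44)                              # reserved
  n_rec <- suppressWarnings(as.integer(trimws(rd(8))))
  rec_dur <- suppressWarnings(as.numeric(trimws(rd(8))))
  ns <- suppressWarnings(as.integer(trimws(rd(4))))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop("corrupt EDF header: ", path)
  }
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16)
  fld(80)                             # transducer
  phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                             # prefiltering
  nspr <- as.integer(fld(8))          # samples per record, per signal
  fld(32)                             # reserved
  idx <- .resolve_channel(channel, labels)

  per_rec <- sum(nspr)
  vals <- readBin(con, "integer", n = per_rec * n_rec, size = 2,
                  signed = TRUE, endian = "little")
  if (length(vals) < per_rec * n_rec) {
    stop("corrupt EDF data section (truncated): ", path)
  }
  offs <- c(0, cumsum(nspr))[idx]
  pick <- as.vector(outer(offs + seq_len(nspr[idx]),
                          (seq_len(n_rec) - 1) * per_rec, `+`))
  dig <- vals[pick]
  scale <- (phys_max[idx] - phys_min[idx]) / (dig_max[idx] - dig_min[idx])
  phys <- (dig - dig_min[idx]) * scale + phys_min[idx]
  phys <- .to_mv(phys, phys_dim[idx])
  fs <- nspr[idx] / rec_dur
  start_time <- .edf_start_time(date_s, time_s)
  ecg_record(phys, fs = fs, start_time = start_time,
             channel_label = labels[idx])
}

.edf_start_time <- function(date_s, time_s) {
  dmy <- suppressWarnings(as.integer(strsplit(date_s, "\\.")[[1]]))
  hms <- suppressWarnings(as.integer(strsplit(time_s, "\\.")[[1]]))
  if (length(dmy) != 3 || length(hms) != 3 || anyNA(dmy) || anyNA(hms)) {
    return(0)
  }
  yy <- dmy[3]
  year <- if (yy >= 85) 1900 + yy else 2000 + yy   # EDF clipping-date rule
  t <- ISOdatetime(year, dmy[2], dmy[1], hms[1], hms[2], hms[3], tz = "UTC")
  as.numeric(t)
}

.resolve_channel <- function(channel, labels, fallback_labels = NULL) {
  if (is.numeric(channel)) {
    idx <- as.integer(channel)
    if (idx < 1 || idx > length(labels)) {
      stop("channel index ", idx, " out of range (", length(labels),
           " channels)")
    }
    return(idx)
  }
  hit <- which(tolower(trimws(labels)) == tolower(trimws(channel)))
  if (!length(hit) && !is.null(fallback_labels)) {
    hit <- which(tolower(trimws(fallback_labels)) == tolower(trimws(channel)))
  }
  if (!length(hit)) {
    stop("channel not found: '", channel, "' (available: ",
         paste(labels[nzchar(labels)], collapse = ", "), ")")
  }
  hit[1]
}

#' Write a minimal WFDB record (format 16)
#'
#' Writes a `.hea`/`.dat` pair with one or more channels, quantized at the
#' given gain (ADC units per mV). Intended for exporting synthetic records
#' and building round-trip fixtures.
#'
#' @param records A single [ecg_record()] or list of them (equal lengths
#'   and rates).
#' @param record_name Record name; files `record_name.hea` / `.dat` are
#'   written in `dir`.
#' @param dir Output directory.
#' @param gain ADC units per mV (default 200).
#' @return Invisibly, the header path.
#' @export
write_wfdb <- function(records, record_name, dir = ".", gain = 200) {
  if (inherits(records, "ecg_record")) records <- list(records)
  n <- length(records[[1]]$samples)
  fs <- records[[1]]$fs
  for (r in records) {
    stopifnot(inherits(r, "ecg_record"), length(r$samples) == n, r$fs == fs)
  }
  datname <- paste0(record_name, ".dat")
  hea <- file.path(dir, paste0(record_name, ".hea"))
  sig_lines <- vapply(records, function(r) {
    sprintf("%s 16 %g/mV 16 0 0 0 0 %s", datname, gain, r$channel_label)
  }, "")
  writeLines(c(sprintf("%s %d %g %d", record_name, length(records), fs, n),
               sig_lines), hea)
  dig <- vapply(records, function(r) {
    as.integer(pmax(pmin(round(r$samples * gain), 32767), -32768))
  }, integer(n))
  inter <- as.integer(t(dig))          # channel-interleaved
  con <- file(file.path(dir, datname), "wb")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  invisible(hea)
}
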