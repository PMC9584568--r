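#' Sleep stage label sets
#'
#' Canonical class orders at each classification level. The 5-class set is
#' the AASM scoring alphabet used by reference hypnograms; the 4/3/2-level
#' sets are the model output spaces. Class order is contractual: argmax
#' ties always break toward the earlier class.
#'
#' @format Character vectors.
#' @name stage_sets
NULL

#' @rdname stage_sets
#' @export
STAGES_AASM5 <- c("W", "N1", "N2", "N3", "R")

#' @rdname stage_sets
#' @export
STAGES_L4 <- c("W", "Light", "Deep", "R")

#' @rdname stage_sets
#' @export
STAGES_L3 <- c("W", "NREM", "R")

#' @rdname stage_sets
#' @export
STAGES_L2 <- c("W", "Sleep")

#' Stage classes at a classification level
#'
#' @param level 2, 3 or 4.
#' @return Character vector of class labels in canonical order.
#' @export
stage_levels <- function(level) {
  switch(as.character(level),
    "2" = STAGES_L2,
    "3" = STAGES_L3,
    "4" = STAGES_L4,
    "5" = STAGES_AASM5,
    stop("unknown classification level: ", level)
  )
}

#' Construct a hypnogram
#'
#' A hypnogram is a sequence of 30-s sleep stage epochs in the 5-class AASM
#' alphabet \{W, N1, N2, N3, R\}. Epoch `i` (0-based) covers the half-open
#' interval `[start_time + 30*i, start_time + 30*(i+1))`.
#'
#' @param labels Character vector of stage labels, all in
#'   \{W, N1, N2, N3, R\}.
#' @param start_time Absolute start time (UTC seconds). Default 0.
#' @param subject_id Subject identifier.
#' @return An object of class `"hypnogram"`.
#' @export
hypnogram <- function(labels, start_time = 0, subject_id = "S1") {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- which(!labels %in% STAGES_AASM5)
  if (length(bad)) {
    stop("invalid stage label '", labels[bad[1]], "' at epoch index ",
         bad[1] - 1L)
  }
  structure(
    list(labels = labels, epoch_len_s = 30L,
         start_time = as.numeric(start_time),
         subject_id = as.character(subject_id)),
    class = "hypnogram"
  )
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = STAGES_AASM5))
  cat(sprintf("<hypnogram> subject %s: %d epochs (%.1f h), start %s s\n",
              x$subject_id, length(x$labels), length(x$labels) / 120,
              format(x$start_time)))
  print(tab)
  invisible(x)
}

#' Epoch onset times of a hypnogram
#'
#' Integer-second arithmetic: onset of epoch `i` (0-based) is exactly
#' `start_time + 30 * i`, with no cumulative drift.
#'
#' @param h A [hypnogram()].
#' @return Numeric vector of onset times (seconds).
#' @export
epoch_onsets <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  h$start_time + 30 * (seq_along(h$labels) - 1)
}

# label maps, kept as named vectors so collapse is a plain lookup
.map_5to4 <- c(W = "W", N1 = "Light", N2 = "Light", N3 = "Deep", R = "R")
.map_4to3 <- c(W = "W", Light = "NREM", Deep = "NREM", R = "R")
.map_4to2 <- c(W = "W", Light = "Sleep", Deep = "Sleep", R = "Sleep")

#' Collapse stage labels across classification levels
#'
#' Applies the hierarchical collapse maps: 5-class AASM to 4-level
#' (N1, N2 -> Light; N3 -> Deep), 4-level to 3-level (Light, Deep -> NREM)
#' and 4-level to 2-level (Light, Deep, R -> Sleep). Wake maps to Wake at
#' every level.
#'
#' @param labels Character vector of labels.
#' @param from Alphabet of `labels`: `"aasm5"` or `"level4"`.
#' @param level Target level: 2, 3 or 4.
#' @return Character vector in the target alphabet.
#' @export
collapse_stages <- function(labels, from = c("aasm5", "level4"), level = 4) {
  from <- match.arg(from)
  labels <- as.character(labels)
  if (from == "aasm5") {
    bad <- setdiff(unique(labels), STAGES_AASM5)
    if (length(bad)) stop("invalid AASM label(s): ", paste(bad, collapse = ", "))
    labels <- unname(.map_5to4[labels])
  } else {
    bad <- setdiff(unique(labels), STAGES_L4)
    if (length(bad)) stop("invalid 4-level label(s): ", paste(bad, collapse = ", "))
  }
  switch(as.character(level),
    "4" = labels,
    "3" = unname(.map_4to3[labels]),
    "2" = unname(.map_4to2[labels]),
    stop("unknown classification level: ", level)
  )
}

#' Grouping of 4-level classes at a coarser level
#'
#' @param level Target level (2, 3 or 4).
#' @return Named character vector mapping each 4-level class to its group.
#' @export
collapse_map <- function(level) {
  switch(as.character(level),
    "4" = stats::setNames(STAGES_L4, STAGES_L4),
    "3" = .map_4to3,
    "2" = .map_4to2,
    stop("unknown classification level: ", level)
  )
}

#' Read a hypnogram CSV
#'
#' Expects the dialect `epoch_index,onset_s,stage` with a header line.
#' Stage tokens are the canonical five \{W, N1, N2, N3, R\}; the common
#' synonyms "Wake" and "REM" (case-insensitive) are normalized to W and R.
#' Any other token (including "N4") is a parse error naming the offending
#' row.
#'
#' @param path File path.
#' @param subject_id Subject identifier to attach; defaults to the file
#'   base name.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "onset_s", "stage")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have header 'epoch_index,onset_s,stage'; got: ",
         paste(names(df), collapse = ","))
  }
  stg <- as.character(df$stage)
  stg[tolower(stg) == "wake"] <- "W"
  stg[tolower(stg) == "rem"] <- "R"
  bad <- which(!stg %in% STAGES_AASM5)
  if (length(bad)) {
    stop("unknown stage token '", df$stage[bad[1]], "' at row ", bad[1],
         " of ", path)
  }
  start_time <- if (nrow(df) > 0) df$onset_s[1] - 30 * df$epoch_index[1] else 0
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  hypnogram(stg, start_time = start_time, subject_id = subject_id)
}

#' Write a hypnogram CSV
#'
#' Inverse of [read_hypnogram()]: writes the `epoch_index,onset_s,stage`
#' dialect so that write-then-read is the identity on the label sequence.
#'
#' @param h A [hypnogram()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  df <- data.frame(
    epoch_index = seq_along(h$labels) - 1L,
    onset_s = epoch_onsets(h),
    stage = h$labels
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
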