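#' Multichannel EEG recording
#'
#' The central data container: a channels x samples matrix of microvolt
#' values at a fixed sampling rate, with named channels and optional interval
#' annotations (state labels such as `rest`, `sfe:s-RB`, `relax`,
#' `regularFE:s-RB`).
#'
#' @param data Numeric matrix, channels x samples.
#' @param rate Sampling rate in samples/second.
#' @param channels Character vector of unique channel names, one per row of
#'   `data`. Defaults to rownames of `data`.
#' @param annotations Data frame with columns `start`, `end` (seconds) and
#'   `label`, or `NULL`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, channels = rownames(data), annotations = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(nrow(data)))
  }
  channels <- as.character(channels)
  if (length(channels) != nrow(data)) {
    stop("channel count must equal the number of data rows", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("all sample values must be finite", call. = FALSE)
  }
  storage.mode(data) <- "double"
  rownames(data) <- channels
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations, ncol(data) / rate)
  }
  structure(
    list(data = data, rate = rate, channels = channels, annotations = annotations),
    class = "eeg_recording"
  )
}

validate_annotations <- function(ann, duration_s) {
  ann <- as.data.frame(ann)
  need <- c("start", "end", "label")
  if (!all(need %in% names(ann))) {
    stop("annotations need columns start, end, label", call. = FALSE)
  }
  ann$start <- as.numeric(ann$start)
  ann$end <- as.numeric(ann$end)
  ann$label <- as.character(ann$label)
  if (any(ann$start >= ann$end)) {
    stop("annotation intervals must satisfy start < end", call. = FALSE)
  }
  if (any(ann$start < 0) || any(ann$end > duration_s + 1e-9)) {
    stop("annotation intervals must lie within the recording duration", call. = FALSE)
  }
  ann[, need]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
    nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate
  ))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotation interval(s)\n", nrow(x$annotations)))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Numeric scalar, seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$rate

#' Extract a time slice of a recording
#'
#' Half-open interval `[from, to)` in seconds; annotations are cropped and
#' re-referenced to the new origin.
#'
#' @param rec An `eeg_recording`.
#' @param from,to Start and end times in seconds.
#' @return An `eeg_recording`.
#' @export
rec_slice <- function(rec, from, to) {
  stopifnot(from < to)
  i0 <- floor(from * rec$rate) + 1L
  i1 <- min(ncol(rec$data), ceiling(to * rec$rate))
  ann <- rec$annotations
  if (!is.null(ann)) {
    keep <- ann$end > from & ann$start < to
    ann <- ann[keep, , drop = FALSE]
    if (nrow(ann)) {
      ann$start <- pmax(ann$start - from, 0)
      ann$end <- pmin(ann$end - from, to - from)
    } else {
      ann <- NULL
    }
  }
  eeg_recording(rec$data[, i0:i1, drop = FALSE], rec$rate, rec$channels, ann)
}

#' Reorder a recording to the canonical montage
#'
#' @param rec An `eeg_recording` whose channels are a superset or permutation
#'   of `montage`.
#' @param montage Character vector of required channel names.
#' @return An `eeg_recording` with rows in montage order.
#' @export
rec_canonicalize <- function(rec, montage = sfe_montage()) {
  missing <- setdiff(montage, rec$channels)
  if (length(missing)) {
    stop(
      sprintf("montage mismatch: missing channel(s) %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  eeg_recording(rec$data[montage, , drop = FALSE], rec$rate, montage, rec$annotations)
}
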