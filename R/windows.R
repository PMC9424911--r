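#' Temporal energy of a sample sequence
#'
#' Sum of squared microvolt samples, the screening statistic of the
#' threshold-comparison step: `E = sum(x_i^2)` over the window.
#'
#' @param samples Non-empty numeric vector (microvolts).
#' @return Energy in microvolts squared.
#' @export
temporal_energy <- function(samples) {
  if (length(samples) == 0) {
    stop("invalid input: empty sample sequence", call. = FALSE)
  }
  sum(samples^2)
}

#' Slice a recording into fixed-length windows
#'
#' Windows are 0-based half-open `[start, start + length)` sample intervals,
#' ordered by start time. A recording shorter than `length` yields an empty
#' list.
#'
#' @param rec An `eeg_recording`.
#' @param length Window length in samples (default 100, i.e. 100 ms at
#'   1000 Hz).
#' @param stride Hop between window starts in samples (default `length`).
#' @return List of `eeg_window` objects (channels x length matrices with
#'   attributes `start` in samples and `band`).
#' @export
slice_windows <- function(rec, length = 100L, stride = length) {
  stopifnot(length >= 1, stride >= 1)
  n <- ncol(rec$data)
  if (n < length) return(list())
  starts <- seq.int(0L, n - length, by = stride)
  band <- attr(rec, "band")
  lapply(starts, function(s) {
    eeg_window(rec$data[, (s + 1L):(s + length), drop = FALSE], band = band,
               start = as.integer(s))
  })
}

#' Starts of sliced windows (0-based samples)
#' @inheritParams slice_windows
#' @return Integer vector of window starts; empty if the recording is shorter
#'   than `length`.
#' @export
window_starts <- function(rec, length = 100L, stride = length) {
  n <- ncol(rec$data)
  if (n < length) return(integer(0))
  seq.int(0L, n - length, by = stride)
}

#' One decoding window
#'
#' A channels x samples matrix (canonically 30 x 100: 100 ms at 1000 Hz)
#' with a band-provenance tag.
#'
#' @param data Numeric matrix, channels x samples, finite.
#' @param band Optional `band_spec` provenance tag.
#' @param start Optional 0-based start sample within the parent recording.
#' @return An `eeg_window`.
#' @export
eeg_window <- function(data, band = NULL, start = NA_integer_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("window values must be finite", call. = FALSE)
  structure(data, class = c("eeg_window", "matrix", "array"),
            band = if (is.null(band)) NULL else as_band(band), start = start)
}

#' @export
print.eeg_window <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf(
    "<eeg_window> %d x %d%s\n", nrow(x), ncol(x),
    if (is.null(b)) "" else sprintf(" band (%g, %g) Hz", b[["low"]], b[["high"]])
  ))
  invisible(x)
}

#' Per-channel temporal energies of a window
#'
#' @param window Channels x samples matrix.
#' @param channels Optional channel subset (names).
#' @return Named numeric vector of energies (uV^2).
#' @export
window_energies <- function(window, channels = NULL) {
  m <- unclass(window)
  if (!is.null(channels)) m <- m[channels, , drop = FALSE]
  rowSums(m^2)
}
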