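#' Zero-phase band-pass filtering
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), giving zero group delay so that 100 ms decoding
#' windows stay aligned with the raw stream.
#'
#' @param rec An `eeg_recording`.
#' @param band A `band_spec` (or numeric `c(low, high)` in Hz).
#' @param order Butterworth order (default 4).
#' @return A filtered `eeg_recording` with the same shape, rate and
#'   annotations; the `band` is recorded in attribute `"band"`.
#' @export
bandpass <- function(rec, band, order = 4) {
  band <- as_band(band)
  nyq <- rec$rate / 2
  if (band[["high"]] >= nyq) {
    stop("invalid band: high edge must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, c(band[["low"]], band[["high"]]) / nyq, type = "pass")
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    out[i, ] <- filtfilt_reflect(bf, rec$data[i, ])
  }
  res <- eeg_recording(out, rec$rate, rec$channels, rec$annotations)
  attr(res, "band") <- band
  res
}

# forward-backward filtering with odd-reflection padding at both ends,
# suppressing the start-up transients of plain filtfilt
filtfilt_reflect <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1, 3000L)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  ext <- c(left, x, right)
  y <- signal::filtfilt(bf, ext)
  y[(pad + 1):(pad + n)]
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  stopifnot(is.numeric(band), length(band) == 2)
  band_spec(band[[1]], band[[2]])
}

#' Downsample a recording
#'
#' Anti-alias low-pass (Butterworth, cutoff 0.45 x target rate, zero phase)
#' followed by index selection onto the target time grid. Duration is
#' preserved to within one sample.
#'
#' @param rec An `eeg_recording`.
#' @param target_rate Target sampling rate in Hz, below `rec$rate`.
#' @return An `eeg_recording` at `target_rate`.
#' @export
downsample <- function(rec, target_rate) {
  if (!is.numeric(target_rate) || target_rate >= rec$rate) {
    stop("invalid input: target_rate must be below the current rate", call. = FALSE)
  }
  bf <- signal::butter(4, (0.45 * target_rate) / (rec$rate / 2), type = "low")
  low <- rec$data
  for (i in seq_len(nrow(low))) {
    low[i, ] <- filtfilt_reflect(bf, rec$data[i, ])
  }
  n_out <- floor(ncol(rec$data) / rec$rate * target_rate)
  # sample the filtered signal at the target grid (nearest source index)
  idx <- pmin(ncol(rec$data), round((seq_len(n_out) - 1) * rec$rate / target_rate) + 1L)
  eeg_recording(low[, idx, drop = FALSE], target_rate, rec$channels, rec$annotations)
}
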