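#' Canonical 30-channel EEG montage
#'
#' Ordered channel names of the 30-electrode scalp montage used throughout the
#' package. All channel-by-channel matrices (connectivity maps, spatial
#' filters, mixing matrices) use this order.
#'
#' @return Character vector of 30 channel names.
#' @export
sfe_montage <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "FC1", "FC2", "FC5",
    "FC6", "Cz", "C3", "C4", "T3", "T4", "CP1", "CP2", "CP5", "CP6",
    "Pz", "P3", "P4", "T5", "T6", "PO3", "PO4", "Oz", "O1", "O2")
}

#' Reference channels used by the screening step
#'
#' The six electrodes closest to the facial muscles. Facial-muscle EMG
#' concentrates its energy on these channels, so the screening step compares
#' their high-band (55-95 Hz) temporal energy against per-channel thresholds.
#'
#' @return Character vector of 6 channel names.
#' @export
sfe_reference_channels <- function() {
  c("Fp1", "Fp2", "F7", "F8", "T3", "T4")
}

#' The nine-way target label space
#'
#' Eight slight facial expressions plus the hold-on class `NON`, in the fixed
#' one-hot encoding order. `s-RB` (slight raise-brow) is the designated
#' state-switching class.
#'
#' @return Character vector of 9 labels.
#' @export
sfe_labels <- function() {
  c("s-RB", "s-FB", "s-LS", "s-RS", "s-OM", "s-S", "s-PM", "s-DM", "NON")
}

#' The eight slight-facial-expression classes (without `NON`)
#' @return Character vector of 8 labels.
#' @export
sfe_classes <- function() sfe_labels()[1:8]

#' Band specification
#'
#' A validated (low, high) pass-band in Hz. The decoding band is (5, 50) Hz;
#' the screening band is (55, 95) Hz.
#'
#' @param low Low edge in Hz.
#' @param high High edge in Hz.
#' @return A `band_spec` object (named numeric vector of length 2).
#' @export
band_spec <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1, length(high) == 1)
  if (!(low > 0 && high > low)) {
    stop("invalid band: need 0 < low < high", call. = FALSE)
  }
  structure(c(low = low, high = high), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> (%g, %g) Hz\n", x[["low"]], x[["high"]]))
  invisible(x)
}

# Default bands of the paradigm.

#' @rdname band_spec
#' @export
decoding_band <- function() band_spec(5, 50)

#' @rdname band_spec
#' @export
screening_band <- function() band_spec(55, 95)
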