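#' Minimal European Data Format (EDF) I/O
#'
#' Reads and writes continuous 16-bit EDF files: one data-record layout with
#' identical sampling rate across signals, physical/digital scaling applied.
#' Intended for interchange of scalp-EEG fixtures; annotations travel in the
#' companion CSV, not in EDF+ annotation signals.
#'
#' @param path File path.
#' @param expected_channels Channel names the file must contain (default: the
#'   canonical 30-channel montage); `NULL` skips the check and keeps file
#'   order.
#' @return `read_edf` returns an `eeg_recording` (channels reordered to
#'   `expected_channels` when given).
#' @export
read_edf <- function(path, expected_channels = sfe_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8); hdr(80); hdr(80); hdr(8); hdr(8)
  hdr(8)                                  # header length, recomputed below
  hdr(44)
  n_rec <- as.integer(hdr(8))
  dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(n) vapply(seq_len(ns), function(i) hdr(n), character(1))
  labels <- field(16)
  field(80); field(8)
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))             # samples per data record
  field(32)
  if (length(unique(spr)) != 1) {
    stop("read_edf supports a single common sampling rate only", call. = FALSE)
  }
  rate <- spr[1] / dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- raw[(pos + 1L):(pos + spr[s])]
      scale <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (seg - dig_min[s]) * scale + phys_min[s]
      pos <- pos + spr[s]
    }
  }
  rec <- eeg_recording(data, rate, labels)
  if (!is.null(expected_channels)) rec <- rec_canonicalize(rec, expected_channels)
  rec
}

#' @rdname read_edf
#' @param rec An `eeg_recording`. Samples are quantized to 16 bits over the
#'   per-channel physical range.
#' @param record_s Data-record duration in seconds (default 1).
#' @export
write_edf <- function(rec, path, record_s = 1) {
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$rate * record_s))
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  used <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  phys_min <- pmin(apply(used, 1, min), -1)
  phys_max <- pmax(apply(used, 1, max), 1)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    x <- as.character(x)
    x <- substr(x, 1, n)
    writeBin(charToRaw(formatC(x, width = -n, flag = " ")), con)
  }
  pad("0", 8); pad("X", 80); pad("sfebci", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44)
  pad(n_rec, 8); pad(format(record_s), 8); pad(ns, 4)
  for (i in seq_len(ns)) pad(rec$channels[i], 16)
  for (i in seq_len(ns)) pad("AgAgCl", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(formatC(phys_min[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) pad(formatC(phys_max[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) pad(dig_min, 8)
  for (i in seq_len(ns)) pad(dig_max, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(spr, 8)
  for (i in seq_len(ns)) pad("", 32)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- used[s, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- round((seg - phys_min[s]) / (phys_max[s] - phys_min[s]) *
                     (dig_max - dig_min) + dig_min)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
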