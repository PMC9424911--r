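#' Read and write recordings as delimited text
#'
#' Fixture dialect: one header row of channel names, one row per sample,
#' UTF-8, "." decimal. The sampling rate travels in a `# rate: <Hz>` comment
#' on the first line. Annotations use a separate CSV of
#' `(start_s, end_s, label)`.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param annotations_path Optional path for the annotation CSV.
#' @return `write_recording_csv` returns `path` invisibly; `read_recording_csv`
#'   returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path, annotations_path = NULL) {
  writeLines(sprintf("# rate: %.10g", rec$rate), path)
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$channels)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  if (!is.null(annotations_path) && !is.null(rec$annotations)) {
    write_annotations_csv(rec$annotations, annotations_path)
  }
  invisible(path)
}

#' @rdname write_recording_csv
#' @param expected_channels Channel names the file must contain; `NULL` skips
#'   the check.
#' @export
read_recording_csv <- function(path, annotations_path = NULL,
                               expected_channels = NULL) {
  first <- readLines(path, n = 1L)
  rate <- NA_real_
  skip <- 0L
  if (startsWith(first, "# rate:")) {
    rate <- as.numeric(sub("# rate:", "", first, fixed = TRUE))
    skip <- 1L
  }
  if (!is.finite(rate)) {
    stop("recording CSV is missing its '# rate:' header line", call. = FALSE)
  }
  dt <- data.table::fread(path, skip = skip, header = TRUE)
  channels <- names(dt)
  if (!is.null(expected_channels)) {
    missing <- setdiff(expected_channels, channels)
    if (length(missing)) {
      stop(sprintf("montage mismatch: missing channel(s) %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  ann <- NULL
  if (!is.null(annotations_path) && file.exists(annotations_path)) {
    ann <- read_annotations_csv(annotations_path)
  }
  eeg_recording(t(as.matrix(dt)), rate, channels, ann)
}

#' @rdname write_recording_csv
#' @param annotations Data frame of `(start, end, label)`.
#' @export
write_annotations_csv <- function(annotations, path) {
  data.table::fwrite(data.table::as.data.table(annotations), path)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_annotations_csv <- function(path) {
  ann <- as.data.frame(data.table::fread(path, header = TRUE))
  names(ann)[1:3] <- c("start", "end", "label")
  ann
}
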