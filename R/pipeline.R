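#' Collect labeled windows from an annotated recording
#'
#' Slices 100-sample windows from annotation intervals, balancing classes by
#' overlap: the per-class stride is chosen so every class yields (up to)
#' `n_per_label` windows, minority classes simply overlapping more. A guard
#' margin is trimmed from each interval so transition samples are excluded.
#'
#' @param rec An annotated `eeg_recording`, already filtered to the band of
#'   interest.
#' @param label_map Function mapping an annotation label to a window label
#'   or `NA` to skip (default: `sfe:<class>` -> class, `rest` -> `NON`).
#' @param n_per_label Target windows per mapped label.
#' @param win_len Window length in samples (default 100).
#' @param margin_s Guard margin trimmed from both interval ends (s).
#' @return List with `windows` (list of channels x win_len matrices) and
#'   `labels` (character vector).
#' @export
collect_windows <- function(rec, label_map = map_step_c, n_per_label = 400,
                            win_len = 100L, margin_s = 0.3) {
  ann <- rec$annotations
  if (is.null(ann)) stop("recording carries no annotations", call. = FALSE)
  mapped <- vapply(ann$label, label_map, character(1), USE.NAMES = FALSE)
  keep <- which(!is.na(mapped))
  segments <- split(keep, mapped[keep])
  windows <- list()
  labels <- character(0)
  for (lab in names(segments)) {
    spans <- lapply(segments[[lab]], function(i) {
      i0 <- floor((ann$start[i] + margin_s) * rec$rate)
      i1 <- floor((ann$end[i] - margin_s) * rec$rate)
      if (i1 - i0 < win_len) NULL else c(i0, i1)
    })
    spans <- Filter(Negate(is.null), spans)
    if (!length(spans)) next
    avail <- sum(vapply(spans, function(s) s[2] - s[1] - win_len + 1, 1))
    stride <- max(1L, floor(avail / n_per_label))
    got <- list()
    for (s in spans) {
      starts <- seq.int(s[1], s[2] - win_len, by = stride)
      got <- c(got, lapply(starts, function(st) {
        rec$data[, (st + 1L):(st + win_len), drop = FALSE]
      }))
    }
    if (length(got) > n_per_label) got <- got[seq_len(n_per_label)]
    windows <- c(windows, got)
    labels <- c(labels, rep(lab, length(got)))
  }
  list(windows = windows, labels = labels)
}

#' @rdname collect_windows
#' @param ann_label One annotation label.
#' @export
map_step_c <- function(ann_label) {
  if (startsWith(ann_label, "sfe:")) sub("^sfe:", "", ann_label)
  else if (ann_label == "rest") "NON"
  else NA_character_
}

#' @rdname collect_windows
#' @export
map_step_b <- function(ann_label) {
  if (ann_label == "sfe:s-RB") "ON"
  else if (startsWith(ann_label, "sfe:") || ann_label %in% c("rest", "relax") ||
           startsWith(ann_label, "regularFE:")) "else"
  else NA_character_
}

#' @rdname collect_windows
#' @export
map_sfe_only <- function(ann_label) {
  if (startsWith(ann_label, "sfe:")) sub("^sfe:", "", ann_label)
  else NA_character_
}

#' Train the full decoder from annotated sessions
#'
#' Fits all three trainable stages from a slight-expression session (plus an
#' optional regular-amplitude session that enriches the switch-on
#' detector's `else` class):
#' the screening threshold bank on screening-band sFE windows, the
#' CSP + scaled-Gaussian-SVM switch-on detector on decoding-band windows
#' (`ON` = slight raise-brow), and the nine-class window network on
#' decoding-band windows of the eight expressions plus `NON` sliced from
#' resting state.
#'
#' @param session_slight Annotated `eeg_recording` with slight trials.
#' @param session_regular Optional annotated recording with
#'   regular-amplitude trials.
#' @param n_per_class Windows per class for the nine-class network.
#' @param n_on Windows per side for the switch-on detector.
#' @param epochs Network training epochs (default 30).
#' @param seed Training seed.
#' @param verbose Print training progress.
#' @return A `decoder_models` list: `bank`, `csp`, `detector`, `net`.
#' @export
train_decoder <- function(session_slight, session_regular = NULL,
                          n_per_class = 400, n_on = 400, epochs = 30,
                          seed = 1L, verbose = FALSE) {
  high <- bandpass(session_slight, screening_band())
  low <- bandpass(session_slight, decoding_band())

  sfe_high <- collect_windows(high, map_sfe_only, n_per_label = 200,
                              win_len = 100L)
  bank <- fit_step_a(sfe_high$windows)

  sb <- collect_windows(low, map_step_b, n_per_label = n_on)
  if (!is.null(session_regular)) {
    low_reg <- bandpass(session_regular, decoding_band())
    reg <- collect_windows(low_reg, function(l) {
      if (startsWith(l, "regularFE:")) "else" else NA_character_
    }, n_per_label = ceiling(n_on / 4))
    sb$windows <- c(sb$windows, reg$windows)
    sb$labels <- c(sb$labels, reg$labels)
  }
  on_w <- sb$windows[sb$labels == "ON"]
  else_w <- sb$windows[sb$labels == "else"]
  csp <- fit_csp(on_w, else_w, pairs = 2)
  feats <- csp_feature_matrix(csp, c(on_w, else_w))
  detector <- train_on_detector(feats, c(rep("ON", length(on_w)),
                                         rep("else", length(else_w))))

  sc <- collect_windows(low, map_step_c, n_per_label = n_per_class)
  net <- train_sfe_net(sc$windows, sc$labels, epochs = epochs, seed = seed,
                       verbose = verbose)
  structure(list(bank = bank, csp = csp, detector = detector, net = net),
            class = "decoder_models")
}

#' @export
print.decoder_models <- function(x, ...) {
  cat("<decoder_models> threshold bank + CSP/SVM switch-on detector + 9-class net\n")
  invisible(x)
}
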