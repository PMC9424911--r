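#' Run the asynchronous four-step decoder over a recording
#'
#' Streams overlapping 100 ms windows through the staged pipeline:
#' Step A screens each raw window by high-band (55-95 Hz) temporal energy;
#' in non-control (NC) mode only the binary switch-on detector (Step B,
#' CSP + SVM on the 5-50 Hz band) runs, in in-control (IC) mode the
#' nine-class network (Step C) runs; every decoded label passes the
#' consistency check (Step D). A valid state-switching label (`s-RB`)
#' toggles NC <-> IC; any other valid label in IC mode is translated via
#' the instruction map and emitted to the device adapter. The decoded-label
#' history is cleared on every transition and (by default) after each
#' emitted instruction.
#'
#' Step outcomes are precomputed for all windows in batch (the staged logic
#' has no feedback from state into the signal), then replayed through the
#' state machine in stream order.
#'
#' @param rec Raw `eeg_recording` (30-channel montage).
#' @param models List with `bank` ([fit_step_a()]), `csp`, `detector`
#'   ([train_on_detector()]) and `net` ([train_sfe_net()]).
#' @param stride_ms Hop between decoded windows in ms (default 10: 90%
#'   overlap).
#' @param n Consistency count (default 20).
#' @param criteria A [criteria_map()].
#' @param instructions An [instruction_map()].
#' @param adapter A device adapter (default [virtual_arm()]); `NULL` logs
#'   instructions without a device.
#' @param start_mode `"NC"` (default) or `"IC"`.
#' @param reset_history Clear the label history after each emitted
#'   instruction (default `TRUE`; it is always cleared on mode
#'   transitions).
#' @param refractory_s Hold-off after each state transition during which no
#'   further trigger can fire (default 3 s, the countdown that separates
#'   control phases in the trial timing). Without it a switching expression
#'   held longer than one consistency span would toggle the interface
#'   straight back.
#' @return An `engine_run`: `events` data frame (one row per window:
#'   counter, time_ms, step_a, decoded label, mode, transition,
#'   instruction), `mode` (final), `adapter`, `instructions_emitted`.
#' @export
step_engine <- function(rec, models, stride_ms = 10, n = 20,
                        criteria = criteria_map("arm"),
                        instructions = instruction_map("arm"),
                        adapter = virtual_arm(), start_mode = "NC",
                        reset_history = TRUE, refractory_s = 3) {
  stopifnot(all(c("bank", "csp", "detector", "net") %in% names(models)))
  win_len <- round(0.1 * rec$rate)
  stride <- max(1L, round(stride_ms / 1000 * rec$rate))
  if (ncol(rec$data) < win_len) {
    warning("stream underrun: recording shorter than one window")
    return(structure(list(events = empty_events(), mode = start_mode,
                          adapter = adapter,
                          instructions_emitted = character(0)),
                     class = "engine_run"))
  }

  high <- bandpass(rec, screening_band())
  low <- bandpass(rec, decoding_band())
  starts <- window_starts(rec, win_len, stride)
  nw <- length(starts)

  # Step A energies via cumulative sums of squared high-band samples
  refs <- names(unclass(models$bank))
  cs <- apply(high$data[refs, , drop = FALSE]^2, 1, cumsum)   # samples x refs
  cs <- rbind(0, cs)
  energies <- cs[starts + win_len + 1L, , drop = FALSE] - cs[starts + 1L, , drop = FALSE]
  colnames(energies) <- refs
  a_res <- step_a_screen_energies(energies, models$bank)

  low_windows <- lapply(starts, function(s) {
    low$data[, (s + 1L):(s + win_len), drop = FALSE]
  })
  feats <- csp_feature_matrix(models$csp, low_windows)
  on_labels <- predict_on(models$detector, feats)
  net_labels <- sfe_net_classify(models$net, low_windows)

  mode <- start_mode
  history <- character(0)
  events <- vector("list", nw)
  emitted <- character(0)
  last_transition_ms <- -Inf
  for (i in seq_len(nw)) {
    t_ms <- (starts[i] + win_len) / rec$rate * 1000
    accepted <- a_res[i] == "accept"
    label <- if (!accepted) "NON"
             else if (mode == "NC") (if (on_labels[i] == "ON") "s-RB" else "NON")
             else net_labels[i]
    history <- c(history, label)
    if (length(history) > n) history <- utils::tail(history, n)
    transition <- NA_character_
    instruction <- NA_character_
    armed <- t_ms - last_transition_ms >= refractory_s * 1000
    if (armed && length(history) == n && label != "NON" &&
        validity_judge(history, label, criteria, n)) {
      if (label == "s-RB") {
        transition <- if (mode == "NC") "NC->IC" else "IC->NC"
        mode <- if (mode == "NC") "IC" else "NC"
        history <- character(0)
        last_transition_ms <- t_ms
      } else if (mode == "IC") {
        instr <- unclass(instructions)[label]
        if (!is.na(instr)) {
          instruction <- unname(instr)
          if (!is.null(adapter)) emit(instruction, adapter)
          emitted <- c(emitted, instruction)
          if (reset_history) history <- character(0)
        }
      }
    }
    events[[i]] <- data.frame(
      counter = i,
      time_ms = t_ms,
      step_a = a_res[i],
      step_b = if (mode == "NC" || !is.na(transition)) on_labels[i] else NA_character_,
      step_c = net_labels[i],
      label = label, mode = mode, transition = transition,
      instruction = instruction, stringsAsFactors = FALSE
    )
  }
  structure(list(events = do.call(rbind, events), mode = mode,
                 adapter = adapter, instructions_emitted = emitted),
            class = "engine_run")
}

empty_events <- function() {
  data.frame(counter = integer(0), time_ms = numeric(0),
             step_a = character(0), step_b = character(0),
             step_c = character(0), label = character(0),
             mode = character(0), transition = character(0),
             instruction = character(0), stringsAsFactors = FALSE)
}

#' @export
print.engine_run <- function(x, ...) {
  tr <- x$events$transition
  cat(sprintf(
    "<engine_run> %d windows, %d transition(s), %d instruction(s), final mode %s\n",
    nrow(x$events), sum(!is.na(tr)), length(x$instructions_emitted), x$mode))
  invisible(x)
}

#' Write an engine event log
#'
#' JSON Lines (one event per line) plus an optional CSV summary of
#' transitions and instructions.
#'
#' @param run An `engine_run`.
#' @param path Output `.jsonl` path.
#' @param summary_path Optional CSV path for the transition/instruction
#'   summary.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(run, path, summary_path = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  ev <- run$events
  for (i in seq_len(nrow(ev))) {
    writeLines(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                na = "null"), con)
  }
  if (!is.null(summary_path)) {
    keep <- !is.na(ev$transition) | !is.na(ev$instruction)
    data.table::fwrite(ev[keep, c("counter", "time_ms", "transition",
                                  "instruction")], summary_path)
  }
  invisible(path)
}
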