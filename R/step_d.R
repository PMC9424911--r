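#' Consistency-checking criteria (Step D)
#'
#' Per-expression consistency fractions: among the latest `n` decoded
#' labels, at least `x` (fraction) must equal the current one before it is
#' translated into an instruction. Defaults follow the two device tasks:
#' `"arm"` (robotic-arm object moving) and `"hand"` (prosthetic-hand water
#' pouring; classes disabled for that task carry criterion 1 and no
#' instruction mapping).
#'
#' @param device `"arm"` or `"hand"`, or pass `values` directly.
#' @param values Named numeric vector over [sfe_classes()], fractions in
#'   (0, 1].
#' @return A `criteria_map` (named numeric vector).
#' @export
criteria_map <- function(device = c("arm", "hand"), values = NULL) {
  if (is.null(values)) {
    device <- match.arg(device)
    values <- switch(device,
      arm = c("s-RB" = 0.95, "s-FB" = 0.95, "s-LS" = 0.45, "s-RS" = 0.45,
              "s-OM" = 0.45, "s-S" = 0.95, "s-PM" = 0.55, "s-DM" = 0.80),
      hand = c("s-RB" = 0.95, "s-FB" = 0.95, "s-LS" = 0.35, "s-RS" = 0.40,
               "s-OM" = 1, "s-S" = 0.95, "s-PM" = 1, "s-DM" = 1)
    )
  }
  stopifnot(all(values > 0), all(values <= 1))
  structure(values, class = "criteria_map")
}

#' Validity judgment of the current decoded label (Step D)
#'
#' The current label (the `n`th, included in `history`) is valid when the
#' fraction of history entries equal to it reaches its consistency
#' criterion (boundary inclusive). `NON` never triggers.
#'
#' @param history Character vector of the latest `n` decoded labels, current
#'   last.
#' @param current The current (`n`th) label.
#' @param criteria A [criteria_map()].
#' @param n Required history length (default 20).
#' @return `TRUE` (valid: translate into an instruction / state switch) or
#'   `FALSE`.
#' @export
validity_judge <- function(history, current, criteria, n = 20) {
  if (length(history) < n) return(FALSE)
  history <- utils::tail(history, n)
  if (current == "NON") return(FALSE)
  x <- unclass(criteria)[current]
  if (is.na(x)) {
    stop(sprintf("configuration error: no consistency criterion for '%s'",
                 current), call. = FALSE)
  }
  sum(history == current) / n >= x
}

#' Theoretical instruction-generation timespan
#'
#' `Ts = 100 + n * ts` (ms): one window length plus `n` consecutive decoded
#' labels at `ts` ms each.
#'
#' @param ts Timespan of one decoded label in ms.
#' @param n Consistency count (default 20).
#' @return Timespan in ms.
#' @export
theoretical_timespan <- function(ts, n = 20) {
  stopifnot(ts >= 0, n >= 0)
  100 + n * ts
}
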