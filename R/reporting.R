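#' Placement intersection-over-union
#'
#' IoU between two axis-aligned equal squares (the target footprint and the
#' placed object footprint) offset by `(dx, dy)`:
#' `overlap = max(0, s - |dx|) * max(0, s - |dy|)`,
#' `union = 2 s^2 - overlap`, reported in percent.
#'
#' @param dx,dy Placement deviation in mm.
#' @param side Square side in mm (default 40: a 4 cm block).
#' @return IoU in percent.
#' @export
placement_iou <- function(dx, dy, side = 40) {
  stopifnot(side > 0)
  overlap <- pmax(0, side - abs(dx)) * pmax(0, side - abs(dy))
  union <- 2 * side^2 - overlap
  100 * overlap / union
}

#' Mean and sample standard deviation
#'
#' @param values Numeric vector (at least 2 values for the standard
#'   deviation).
#' @param digits Rounding digits (half-up) for the returned values; `NULL`
#'   for no rounding.
#' @return Named vector `c(mean, sd)`; `sd` uses the n-1 denominator.
#' @export
aggregate_stats <- function(values, digits = 2) {
  stopifnot(length(values) >= 2)
  out <- c(mean = mean(values), sd = stats::sd(values))
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Round half away from zero
#'
#' Decimal rounding where `.5` ties go up in magnitude (the convention of
#' the reported percentage tables), unlike `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # snap float representations (e.g. 1.005 stored as 1.00499...) before the
  # half-up decision
  y <- round(abs(x) * p, 9)
  sign(x) * floor(y + 0.5) / p
}
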