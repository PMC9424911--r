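#' Sample entropy
#'
#' `SampEn(m, r, N) = -ln(A^m(r) / B^m(r))` where `B` counts template pairs
#' of length `m` and `A` of length `m + 1` within Chebyshev tolerance `r`,
#' excluding self-matches. `r` is computed as `r_factor` times the standard
#' deviation of the sequence. Irregular (EMG-dominated) signals score high;
#' rhythmic EEG components score low. A constant sequence returns 0 (every
#' template matches); if no `m + 1` template matches exist the result is
#' `Inf`.
#'
#' @param x Numeric sequence of length `N > m + 1`.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of `sd(x)` (default 0.2).
#' @return Nonnegative value (possibly `Inf`).
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  if (n <= m + 1) stop("invalid input: sequence too short for SampEn", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0)          # constant: all templates match, -ln(1) = 0
  r <- r_factor * s
  # distance between scalar samples; templates compared over N - m starts
  nt <- n - m
  d <- abs(outer(x, x, "-")) <= r     # n x n logical
  # match of length-k templates starting at i, j: all(d[i + 0:(k-1), j + 0:(k-1)])
  acc <- d[1:nt, 1:nt]
  for (k in seq_len(m - 1)) {
    acc <- acc & d[1:nt + k, 1:nt + k]
  }
  B <- (sum(acc) - nt) / 2            # exclude self-matches, unordered pairs
  accA <- acc & d[1:nt + m, 1:nt + m]
  A <- (sum(accA) - nt) / 2
  if (B == 0) return(Inf)
  if (A == 0) return(Inf)
  -log(A / B)
}
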