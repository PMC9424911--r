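#' Multivariate autoregressive (MVAR) model
#'
#' Container for an order-`m` MVAR model
#' `y(n) = sum_r A_r y(n - r) + w(n)` with innovation covariance `noise_cov`
#' (whose diagonal, `lambda`, scales the generalized connectivity measure).
#'
#' @param order Model order `m >= 1`.
#' @param coeffs List of `m` square coefficient matrices `A_r`.
#' @param noise_cov Innovation covariance matrix (symmetric PSD).
#' @return An `mvar_model`.
#' @export
mvar_model <- function(order, coeffs, noise_cov) {
  stopifnot(order >= 1, length(coeffs) == order)
  ch <- nrow(coeffs[[1]])
  for (A in coeffs) {
    stopifnot(is.matrix(A), nrow(A) == ch, ncol(A) == ch, all(is.finite(A)))
  }
  noise_cov <- (noise_cov + t(noise_cov)) / 2
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("noise_cov must be positive semidefinite", call. = FALSE)
  }
  structure(list(order = order, coeffs = coeffs, noise_cov = noise_cov,
                 lambda = diag(noise_cov)),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channels\n",
              x$order, nrow(x$coeffs[[1]])))
  invisible(x)
}

#' Fit an MVAR model by least squares
#'
#' De-means each channel, stacks lagged regressors and solves the
#' multivariate least-squares problem; the residual covariance is reported
#' as the innovation covariance.
#'
#' @param data Channels x samples numeric matrix (or `eeg_recording`).
#' @param order Model order `m`.
#' @return An [mvar_model()].
#' @export
fit_mvar <- function(data, order) {
  if (inherits(data, "eeg_recording")) data <- data$data
  data <- as.matrix(data)
  ch <- nrow(data)
  n <- ncol(data)
  if (n <= ch * order + 10) {
    stop("singular fit: too few samples for the requested order", call. = FALSE)
  }
  data <- data - rowMeans(data)
  n_eq <- n - order
  # regressor matrix: rows = time, cols = ch*order (lag 1..m blocks)
  X <- matrix(0, n_eq, ch * order)
  for (r in seq_len(order)) {
    X[, ((r - 1) * ch + 1):(r * ch)] <- t(data[, (order - r + 1):(n - r), drop = FALSE])
  }
  Y <- t(data[, (order + 1):n, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("singular fit: rank-deficient regressors", call. = FALSE)
  }
  B <- qr.coef(qrX, Y)                     # (ch*order) x ch
  resid <- Y - X %*% B
  sigma <- crossprod(resid) / n_eq
  coeffs <- lapply(seq_len(order), function(r) {
    t(B[((r - 1) * ch + 1):(r * ch), , drop = FALSE])
  })
  mvar_model(order = order, coeffs = coeffs, noise_cov = sigma)
}

#' Select the MVAR order by the Akaike information criterion
#'
#' `AIC(m) = ln det(Sigma_w(m)) + 2 m ch^2 / N`, minimized over
#' `1..max_order`.
#'
#' @param data Channels x samples matrix (or `eeg_recording`).
#' @param max_order Largest candidate order.
#' @param orders Optional explicit candidate set (overrides `max_order`).
#' @return The selected order (integer).
#' @export
select_order <- function(data, max_order = 10, orders = seq_len(max_order)) {
  if (inherits(data, "eeg_recording")) data <- data$data
  ch <- nrow(data)
  n <- ncol(data)
  aic <- vapply(orders, function(m) {
    fit <- fit_mvar(data, m)
    d <- determinant(fit$noise_cov, logarithm = TRUE)
    as.numeric(d$modulus) + 2 * m * ch^2 / n
  }, numeric(1))
  orders[which.min(aic)]
}

#' Spectral transform of an MVAR model
#'
#' `A(f) = I - sum_r A_r exp(-i 2 pi f r / rate)` evaluated on a frequency
#' grid; at zero coefficients it is the identity at every frequency.
#'
#' @param model An [mvar_model()].
#' @param freqs Frequencies in Hz, inside (0, Nyquist).
#' @param rate Sampling rate in Hz the model was fitted at (default 1000).
#' @return A `spectral_matrix`: complex array ch x ch x length(freqs) with
#'   attribute `freqs`.
#' @export
spectral_matrix <- function(model, freqs, rate = 1000) {
  ch <- nrow(model$coeffs[[1]])
  out <- array(0i, dim = c(ch, ch, length(freqs)))
  I <- diag(ch)
  for (k in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[k] * seq_len(model$order) / rate)
    Af <- I
    for (r in seq_len(model$order)) Af <- Af - model$coeffs[[r]] * z[r]
    out[, , k] <- Af
  }
  structure(out, freqs = freqs, class = c("spectral_matrix", "array"))
}

#' Generalized orthogonalized partial directed coherence
#'
#' For each frequency and channel pair `p != q` computes
#' `(1 / lambda_p^2) * |Re A_pq(f)| / (a_q^H S^-1 a_q) *
#'  |Im A_pq(f)| / (a_q^H S^-1 a_q)`
#' where `a_q` is the q-th column of the spectral matrix, `S` the innovation
#' covariance and `lambda_p` its p-th diagonal entry. Entry `(p, q)` is the
#' flow q -> p; the diagonal is `NaN`. The product of real- and
#' imaginary-part magnitudes suppresses zero-lag (volume-conduction)
#' coupling, and the `lambda` scaling makes the measure robust to per-channel
#' amplitude scale.
#'
#' @param model An [mvar_model()].
#' @param freqs Frequencies in Hz (default 1 Hz grid to 499 Hz).
#' @param rate Sampling rate in Hz (default 1000).
#' @param sqrt_denominator If `TRUE` uses the square-rooted quadratic form in
#'   each factor's denominator (classical generalized-PDC normalization);
#'   default `FALSE` uses the quadratic form as is.
#' @return A `gopdc_map`: nonnegative array ch x ch x length(freqs), diagonal
#'   `NaN`, with attribute `freqs`.
#' @export
gopdc <- function(model, freqs = seq(1, 499), rate = 1000,
                  sqrt_denominator = FALSE) {
  S <- model$noise_cov
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    warning("singular noise covariance; applying ridge regularization")
    S <- S + diag(1e-8 * mean(diag(S)), nrow(S))
    Sinv <- tryCatch(solve(S), error = function(e) {
      stop("singular covariance: cannot invert even after regularization",
           call. = FALSE)
    })
  }
  lam2 <- diag(model$noise_cov)^2
  A <- spectral_matrix(model, freqs, rate)
  ch <- nrow(model$coeffs[[1]])
  out <- array(NA_real_, dim = c(ch, ch, length(freqs)))
  for (k in seq_along(freqs)) {
    Af <- A[, , k]
    for (q in seq_len(ch)) {
      aq <- Af[, q]
      denom <- Re(Conj(aq) %*% Sinv %*% aq)[1]
      if (sqrt_denominator) denom <- sqrt(denom)
      out[, q, k] <- (1 / lam2) * abs(Re(Af[, q])) * abs(Im(Af[, q])) / denom^2
    }
    diag(out[, , k]) <- NaN
    if (ch == 1) out[1, 1, k] <- NaN
  }
  dimnames(out) <- list(rownames(model$coeffs[[1]]), rownames(model$coeffs[[1]]), NULL)
  structure(out, freqs = freqs, class = c("gopdc_map", "array"))
}

#' Sliding-window gOPDC
#'
#' Refits the MVAR model in consecutive windows and computes the gOPDC map
#' per window, a sliding-window stand-in for time-varying estimation.
#'
#' @param rec An `eeg_recording`.
#' @param win_s Window length in seconds (default 0.5).
#' @param step_s Hop between window starts in seconds (default `win_s`).
#' @param order MVAR order for each window fit.
#' @param freqs Frequencies in Hz.
#' @return List with `maps` (list of `gopdc_map`s) and `centers` (window
#'   centre times, seconds).
#' @export
sliding_gopdc <- function(rec, win_s = 0.5, step_s = win_s, order = 6,
                          freqs = seq(1, floor(rec$rate / 2) - 1)) {
  n_win <- round(win_s * rec$rate)
  if (ncol(rec$data) < n_win) stop("recording shorter than one window", call. = FALSE)
  starts <- window_starts(rec, n_win, max(1L, round(step_s * rec$rate)))
  maps <- lapply(starts, function(s) {
    seg <- rec$data[, (s + 1):(s + n_win), drop = FALSE]
    gopdc(fit_mvar(seg, order), freqs, rec$rate)
  })
  list(maps = maps, centers = (starts + n_win / 2) / rec$rate)
}

#' Average a gOPDC map over frequency bands
#'
#' @param map A `gopdc_map` (ch x ch x freq with attribute `freqs`).
#' @param bands Named list of `c(low, high)` Hz pairs; defaults to the three
#'   representative EEG bands low (4, 12), medium (12, 30) and high
#'   (30, 50) Hz.
#' @return Named list of ch x ch matrices (arithmetic mean over frequency
#'   bins inside each band, edges inclusive).
#' @export
band_average <- function(map, bands = list(low = c(4, 12),
                                           medium = c(12, 30),
                                           high = c(30, 50))) {
  freqs <- attr(map, "freqs")
  lapply(bands, function(b) {
    sel <- which(freqs >= b[1] & freqs <= b[2])
    if (!length(sel)) stop("band contains no frequency bins", call. = FALSE)
    apply(map[, , sel, drop = FALSE], c(1, 2), mean)
  })
}

#' Resting-state baseline threshold and masking
#'
#' The baseline is the given percentile (default 99th) of all finite values
#' of the resting-state maps, computed as an order statistic; masking keeps
#' only strictly larger values.
#'
#' @param resting_maps A `gopdc_map`, a matrix, or a list of them.
#' @param percentile Percentile in (0, 100], default 99.
#' @return `baseline_threshold` returns a scalar; `apply_threshold` returns
#'   the map with values at or below the threshold set to `NA`.
#' @export
baseline_threshold <- function(resting_maps, percentile = 99) {
  if (!is.list(resting_maps)) resting_maps <- list(resting_maps)
  v <- unlist(lapply(resting_maps, function(m) {
    m <- as.numeric(m)
    m[is.finite(m)]
  }))
  stats::quantile(v, percentile / 100, type = 1, names = FALSE)
}

#' @rdname baseline_threshold
#' @param map Map or matrix to mask.
#' @param thr Threshold from [baseline_threshold()].
#' @export
apply_threshold <- function(map, thr) {
  out <- map
  out[!is.na(out) & out <= thr] <- NA_real_
  out
}

#' Scale a band matrix so its largest finite entry is 1
#'
#' Reporting-layer normalization for connectivity matrices.
#' @param m Numeric matrix.
#' @return Rescaled matrix.
#' @export
normalize_max <- function(m) {
  mx <- max(m[is.finite(m)])
  if (mx > 0) m / mx else m
}
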