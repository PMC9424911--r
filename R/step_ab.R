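#' Fit the screening threshold bank (Step A)
#'
#' For each of the six facial-muscle reference channels the threshold is 105%
#' of the highest temporal energy observed over all slight-facial-expression
#' training windows (windows must be filtered to the 55-95 Hz screening
#' band). A later window is rejected as obvious non-sFE when any reference
#' channel's energy exceeds its own threshold.
#'
#' @param training_windows List of channels x samples windows in the
#'   screening band (rows named; all eight sFE classes pooled).
#' @param reference_channels Channel names of the bank (default
#'   [sfe_reference_channels()]).
#' @param margin Multiplier over the training maximum (default 1.05).
#' @return A `threshold_bank`: named numeric vector of uV^2 thresholds with
#'   attributes `band` and `margin`.
#' @export
fit_step_a <- function(training_windows,
                       reference_channels = sfe_reference_channels(),
                       margin = 1.05) {
  stopifnot(length(training_windows) >= 1)
  w1 <- training_windows[[1]]
  missing <- setdiff(reference_channels, rownames(w1))
  if (length(missing)) {
    stop(sprintf("montage mismatch: missing channel(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  maxima <- Reduce(pmax, lapply(training_windows, function(w) {
    window_energies(w, reference_channels)
  }))
  structure(margin * maxima, class = "threshold_bank",
            band = screening_band(), margin = margin)
}

#' Screen one window against the threshold bank (Step A)
#'
#' @param window Channels x samples window filtered to the screening band.
#' @param bank A `threshold_bank` from [fit_step_a()].
#' @return `"accept"` (probably an sFE) or `"reject"` (obvious non-sFE).
#' @export
step_a_screen <- function(window, bank) {
  e <- window_energies(window, names(unclass(bank)))
  if (any(e > unclass(bank))) "reject" else "accept"
}

# vectorized screen over precomputed per-window reference energies
step_a_screen_energies <- function(energy_matrix, bank) {
  # energy_matrix: windows x reference-channels
  thr <- unclass(bank)[colnames(energy_matrix)]
  ifelse(rowSums(sweep(energy_matrix, 2, thr, ">")) > 0, "reject", "accept")
}

#' Composite score for threshold-setting methods
#'
#' `100 / (1/AR + 1/RR + Ts)`: the harmonic-style score combining the
#' correct-acceptance rate, correct-rejection rate and per-window timespan
#' (ms), on the percent-like scale of the comparison table.
#'
#' @param AR Correct acceptance rate, fraction in (0, 1].
#' @param RR Correct rejection rate, fraction in (0, 1].
#' @param Ts Timespan per window in ms (>= 0).
#' @return Score (numeric scalar).
#' @export
threshold_method_score <- function(AR, RR, Ts) {
  stopifnot(AR > 0, AR <= 1, RR > 0, RR <= 1, Ts >= 0)
  100 / (1 / AR + 1 / RR + Ts)
}

# ---- common spatial patterns (Step B features) ----------------------------

#' Fit common spatial patterns for two classes
#'
#' Per-window channel covariances are trace-normalized and averaged per
#' class; the spatial filters are the generalized eigenvectors of
#' `C1 w = lambda (C1 + C2) w`, keeping the `pairs` most extreme
#' eigenvectors from each end (default 2 pairs, i.e. 4 filters).
#'
#' @param windows_a,windows_b Lists of channels x samples windows (filtered
#'   to the 5-50 Hz decoding band), one list per class.
#' @param pairs Number of filter pairs `m` (default 2).
#' @return A `csp_model` with `filters` (2m x channels) and the class mean
#'   covariances.
#' @export
fit_csp <- function(windows_a, windows_b, pairs = 2) {
  stopifnot(length(windows_a) >= 2, length(windows_b) >= 2)
  C1 <- mean_normalized_cov(windows_a)
  C2 <- mean_normalized_cov(windows_b)
  Cc <- C1 + C2
  # whiten the composite covariance, then eigendecompose the whitened C1
  eg <- eigen(Cc, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values)
  P <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  S1 <- P %*% C1 %*% t(P)
  eg1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  Wfull <- eg1$vectors
  k <- ncol(Wfull)
  sel <- c(seq_len(pairs), (k - pairs + 1):k)
  filters <- t(Wfull[, sel, drop = FALSE]) %*% P     # 2m x channels
  rownames(filters) <- paste0("csp", seq_len(2 * pairs))
  structure(list(filters = filters, pairs = pairs, cov_a = C1, cov_b = C2,
                 eigenvalues = eg1$values[sel]),
            class = "csp_model")
}

mean_normalized_cov <- function(windows) {
  covs <- lapply(windows, function(w) {
    m <- unclass(w)
    m <- m - rowMeans(m)
    cv <- tcrossprod(m)
    cv / sum(diag(cv))
  })
  Reduce(`+`, covs) / length(covs)
}

#' CSP feature vector of one window
#'
#' `f_k = log(var(Y_k)) / sum_k log(var(Y_k))` over the `2m` spatially
#' filtered signals `Y = W X`; by construction the features sum to 1.
#'
#' @param model A `csp_model`.
#' @param window Channels x samples matrix in the decoding band.
#' @return Numeric feature vector of length `2m`.
#' @export
csp_features <- function(model, window) {
  m <- unclass(window)
  Y <- model$filters %*% (m - rowMeans(m))
  v <- apply(Y, 1, stats::var)
  if (any(v <= 0)) stop("degenerate feature: zero filtered variance", call. = FALSE)
  lv <- log(v)
  denom <- sum(lv)
  if (abs(denom) < 1e-9) stop("degenerate feature: log-variance sum ~ 0", call. = FALSE)
  lv / denom
}

#' @rdname csp_features
#' @param windows List of windows.
#' @return `csp_feature_matrix` returns an n x 2m matrix.
#' @export
csp_feature_matrix <- function(model, windows) {
  t(vapply(windows, function(w) csp_features(model, w),
           numeric(nrow(model$filters))))
}

# ---- scaled-Gaussian SVM (Step B classifier) ------------------------------

#' Kernel scale of the scaled Gaussian kernel
#'
#' `gamma = 1 / (n_feature * var(X))` with the variance pooled over every
#' entry of the feature matrix.
#'
#' @param features n x p numeric feature matrix.
#' @return Scalar `gamma`.
#' @export
kernel_scale <- function(features) {
  features <- as.matrix(features)
  1 / (ncol(features) * stats::var(as.vector(features)))
}

#' Train the switch-on detector (Step B)
#'
#' Binary SVM with radial kernel at the scaled-Gaussian `gamma` of
#' [kernel_scale()], cost 1, no feature standardization. `"ON"` windows are
#' the state-switching expression (slight raise-brow); everything else
#' (resting, relaxing, other sFEs, regular-amplitude expressions) is
#' `"else"`.
#'
#' @param features n x 4 CSP feature matrix.
#' @param labels Factor or character vector with levels `ON` / `else`.
#' @return An `on_detector` holding the SVM and `gamma`.
#' @export
train_on_detector <- function(features, labels) {
  labels <- factor(as.character(labels), levels = c("ON", "else"))
  stopifnot(all(table(labels) >= 2))
  g <- kernel_scale(features)
  fit <- e1071::svm(x = as.matrix(features), y = labels, kernel = "radial",
                    gamma = g, cost = 1, scale = FALSE)
  structure(list(svm = fit, gamma = g), class = "on_detector")
}

#' @rdname train_on_detector
#' @param detector An `on_detector`.
#' @param newdata Feature matrix to classify.
#' @return Character vector of `"ON"` / `"else"`.
#' @export
predict_on <- function(detector, newdata) {
  as.character(stats::predict(detector$svm, as.matrix(newdata)))
}
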