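#' Entropy parameters for component labeling
#'
#' @param m Template length (default 2).
#' @param r_factor Tolerance fraction of the sequence's standard deviation
#'   (default 0.2).
#' @param threshold Sample-entropy threshold above which a component is
#'   labeled as EMG-dominated (default 0.45).
#' @return An `entropy_params` list.
#' @export
entropy_params <- function(m = 2, r_factor = 0.2, threshold = 0.45) {
  stopifnot(m >= 1, r_factor > 0)
  structure(list(m = m, r_factor = r_factor, threshold = threshold),
            class = "entropy_params")
}

#' Decompose a recording into components
#'
#' Two routes: `"fastICA"` separates the multichannel signal into up to
#' channel-count independent components (symmetric fixed-point FastICA,
#' `tanh` or Gauss contrast); `"NA-MEMD"` decomposes every channel into
#' intrinsic mode functions by cubic-spline sifting, optionally
#' noise-assisted by ensemble averaging over white-noise perturbed copies.
#'
#' @param rec An `eeg_recording` (or channels x samples matrix).
#' @param method `"fastICA"` or `"NA-MEMD"`.
#' @param contrast FastICA nonlinearity: `"tanh"` (default) or `"gauss"`.
#' @param n_components FastICA component cap (default: channel count).
#' @param max_iter,tol FastICA iteration controls.
#' @param max_imfs,ensemble_size,noise_amp EMD controls: IMF cap, ensemble
#'   size (1 = plain EMD), assist-noise amplitude as a fraction of the
#'   channel standard deviation.
#' @param seed Seed for the FastICA start and the assist noise.
#' @return A `component_set`: for ICA, `components` (k x samples), `mixing`
#'   (channels x k) and `center`; for MEMD, `imfs` (per-channel list of
#'   matrices whose last row is the sift residue).
#' @export
decompose <- function(rec, method = c("fastICA", "NA-MEMD"),
                      contrast = c("tanh", "gauss"), n_components = NULL,
                      max_iter = 200, tol = 1e-6,
                      max_imfs = 10, ensemble_size = 1, noise_amp = 0.1,
                      seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  rate <- if (inherits(rec, "eeg_recording")) rec$rate else NA_real_
  channels <- if (inherits(rec, "eeg_recording")) rec$channels else rownames(x)
  if (method == "fastICA") {
    if (nrow(x) < 2) {
      stop("invalid input: FastICA needs at least 2 channels", call. = FALSE)
    }
    fit <- fastica_fit(x, match.arg(contrast), n_components, max_iter, tol, seed)
    structure(list(method = "fastICA", components = fit$S, mixing = fit$A,
                   center = fit$center, channels = channels, rate = rate),
              class = "component_set")
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    imfs <- lapply(seq_len(nrow(x)), function(i) {
      memd_channel(x[i, ], max_imfs, ensemble_size, noise_amp)
    })
    names(imfs) <- channels
    structure(list(method = "NA-MEMD", imfs = imfs, channels = channels,
                   rate = rate, n_samples = ncol(x)),
              class = "component_set")
  }
}

#' @export
print.component_set <- function(x, ...) {
  if (x$method == "fastICA") {
    cat(sprintf("<component_set> FastICA: %d components x %d samples\n",
                nrow(x$components), ncol(x$components)))
  } else {
    cat(sprintf("<component_set> NA-MEMD: %d channels, %s IMFs each\n",
                length(x$imfs),
                paste(range(vapply(x$imfs, nrow, 1L) - 1L), collapse = "-")))
  }
  invisible(x)
}

fastica_fit <- function(x, contrast, n_components, max_iter, tol, seed) {
  ch <- nrow(x)
  n <- ncol(x)
  center <- rowMeans(x)
  xc <- x - center
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > 1e-10 * max(eg$values))
  k <- min(length(keep), if (is.null(n_components)) ch else n_components)
  keep <- keep[seq_len(k)]
  K <- diag(1 / sqrt(eg$values[keep]), k) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% xc                             # whitened, k x n
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  g <- switch(contrast,
    tanh = function(u) list(g = tanh(u), dg = 1 - tanh(u)^2),
    gauss = function(u) list(g = u * exp(-u^2 / 2), dg = (1 - u^2) * exp(-u^2 / 2))
  )
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), k) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  it <- 0
  repeat {
    it <- it + 1
    U <- W %*% Z
    gg <- g(U)
    W_new <- gg$g %*% t(Z) / n - diag(rowMeans(gg$dg), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
    if (it >= max_iter) {
      stop(sprintf("FastICA did not converge in %d iterations", max_iter),
           call. = FALSE)
    }
  }
  S <- W %*% Z
  # mixing matrix maps components back to sensors: x ~ A S + center
  WK <- W %*% K                              # k x ch unmixing
  A <- t(WK) %*% solve(WK %*% t(WK))
  list(S = S, A = A, center = center, iterations = it)
}

# ---- empirical mode decomposition -----------------------------------------

local_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1
  turn <- diff(s)
  maxima <- which(turn < 0) + 1L
  minima <- which(turn > 0) + 1L
  list(max = maxima, min = minima)
}

envelope <- function(idx, val, n) {
  # extend with boundary knots mirroring the outermost extrema
  xi <- c(1 - (idx[2] - idx[1]), idx, n + (idx[length(idx)] - idx[length(idx) - 1]))
  yi <- c(val[2], val, val[length(val) - 1])
  stats::spline(xi, yi, xout = seq_len(n), method = "fmm")$y
}

sift_imf <- function(x, max_sifts = 50, sd_thresh = 0.2) {
  h <- x
  n <- length(x)
  for (s in seq_len(max_sifts)) {
    ex <- local_extrema(h)
    if (length(ex$max) < 2 || length(ex$min) < 2) return(NULL)
    upper <- envelope(ex$max, h[ex$max], n)
    lower <- envelope(ex$min, h[ex$min], n)
    m <- (upper + lower) / 2
    h_new <- h - m
    crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (crit < sd_thresh) break
  }
  h
}

emd <- function(x, max_imfs = 10) {
  residue <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    ex <- local_extrema(residue)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
    imf <- sift_imf(residue)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1]] <- imf
    residue <- residue - imf
  }
  rbind(if (length(imfs)) do.call(rbind, imfs), residue)
}

memd_channel <- function(x, max_imfs, ensemble_size, noise_amp) {
  if (ensemble_size <= 1) return(emd(x, max_imfs))
  s <- stats::sd(x)
  stack <- NULL
  n_rows <- Inf
  runs <- lapply(seq_len(ensemble_size), function(e) {
    emd(x + stats::rnorm(length(x), sd = noise_amp * s), max_imfs)
  })
  n_rows <- min(vapply(runs, nrow, 1L))
  Reduce(`+`, lapply(runs, function(m) {
    rbind(m[seq_len(n_rows - 1), , drop = FALSE],
          colSums(m[n_rows:nrow(m), , drop = FALSE]))
  })) / ensemble_size
}

# ---- labeling and reconstruction ------------------------------------------

#' Label components as EEG or EMG by sample entropy
#'
#' A component is labeled `"EMG"` when its sample entropy exceeds the
#' threshold, `"EEG"` otherwise.
#'
#' @param cs A `component_set` from [decompose()].
#' @param params An [entropy_params()].
#' @return For ICA: character vector per component. For MEMD: per-channel
#'   list of character vectors (one per IMF row, residue included).
#' @export
label_components <- function(cs, params = entropy_params()) {
  lab <- function(v) {
    se <- sample_entropy(v, params$m, params$r_factor)
    if (is.finite(se) && se > params$threshold) "EMG"
    else if (!is.finite(se)) "EMG" else "EEG"
  }
  if (cs$method == "fastICA") {
    apply(cs$components, 1, lab)
  } else {
    lapply(cs$imfs, function(m) apply(m, 1, lab))
  }
}

#' Sample entropy of every component
#' @inheritParams label_components
#' @return Numeric vector (ICA) or per-channel list (MEMD).
#' @export
component_entropies <- function(cs, params = entropy_params()) {
  f <- function(v) sample_entropy(v, params$m, params$r_factor)
  if (cs$method == "fastICA") apply(cs$components, 1, f)
  else lapply(cs$imfs, function(m) apply(m, 1, f))
}

#' Reconstruct the cleaned recording
#'
#' Sums or remixes only the components labeled `"EEG"`, discarding
#' EMG-dominated ones.
#'
#' @param cs A `component_set`.
#' @param labels Labels from [label_components()].
#' @return An `eeg_recording` (rate taken from the decomposed input; 1000 Hz
#'   if unknown).
#' @export
reconstruct_clean <- function(cs, labels) {
  rate <- if (is.finite(cs$rate)) cs$rate else 1000
  if (cs$method == "fastICA") {
    keep <- which(labels == "EEG")
    n <- ncol(cs$components)
    x <- matrix(0, length(cs$channels), n)
    if (length(keep)) {
      x <- cs$mixing[, keep, drop = FALSE] %*% cs$components[keep, , drop = FALSE]
    }
    if (length(keep)) x <- x + cs$center
    eeg_recording(x, rate, cs$channels)
  } else {
    x <- t(vapply(seq_along(cs$imfs), function(i) {
      keep <- which(labels[[i]] == "EEG")
      if (!length(keep)) return(numeric(cs$n_samples))
      colSums(cs$imfs[[i]][keep, , drop = FALSE])
    }, numeric(cs$n_samples)))
    eeg_recording(x, rate, cs$channels)
  }
}

#' Per-channel energy reduction after cleaning
#'
#' `100 * (1 - energy(cleaned) / energy(original))` per channel; the summary
#' statistic of artifact removal.
#'
#' @param original,cleaned `eeg_recording`s (or matrices) of equal shape.
#' @return Named numeric vector of percentages.
#' @export
energy_reduction_ratio <- function(original, cleaned) {
  a <- if (inherits(original, "eeg_recording")) original$data else as.matrix(original)
  b <- if (inherits(cleaned, "eeg_recording")) cleaned$data else as.matrix(cleaned)
  stopifnot(all(dim(a) == dim(b)))
  e0 <- rowSums(a^2)
  e1 <- rowSums(b^2)
  out <- 100 * (1 - e1 / e0)
  names(out) <- rownames(a)
  out
}
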