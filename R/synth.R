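#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the statistical structure the decoder assumes:
#' a stationary multichannel background (stable MVAR(6) plus 1/f-shaped
#' noise), eight distinguishable slight-facial-expression (sFE) classes as
#' narrow-band oscillations (centre frequencies within 8-45 Hz) with
#' class-specific spatial patterns, and EMG-like broadband bursts (20-95 Hz)
#' concentrated on the six facial-muscle reference channels. The
#' "regular-amplitude" expression variant scales the burst amplitude by
#' `artifact_gain_regular / artifact_gain_slight` (>= 3).
#'
#' @param n_channels Number of channels (default 30, canonical montage).
#' @param rate Sampling rate in Hz (default 1000).
#' @param artifact_gain_slight Burst amplitude gain for slight expressions.
#' @param artifact_gain_regular Burst amplitude gain for regular-amplitude
#'   expressions; must be at least `3 * artifact_gain_slight`.
#' @param background_order MVAR order of the background process.
#' @param noise_sd Innovation standard deviation of the background (uV).
#' @param pink_sd Standard deviation of the added 1/f noise (uV).
#' @param osc_amplitude Amplitude of the class oscillation (uV).
#' @param burst_sd Pre-gain standard deviation of the EMG burst source (uV).
#' @param seed Integer seed; all randomness (background model, class
#'   patterns, per-trial streams) derives from it via a counter-based split.
#' @return A `synth_config` object with materialized class patterns and
#'   background model.
#' @export
synth_config <- function(n_channels = 30, rate = 1000,
                         artifact_gain_slight = 1.0,
                         artifact_gain_regular = 5.0,
                         background_order = 6,
                         noise_sd = 3, pink_sd = 8,
                         osc_amplitude = 14, burst_sd = 10,
                         seed = 42L) {
  if (artifact_gain_slight > 0 &&
      artifact_gain_regular / artifact_gain_slight < 3) {
    stop("artifact_gain_regular must be at least 3x artifact_gain_slight",
         call. = FALSE)
  }
  channels <- if (n_channels == 30) sfe_montage() else paste0("ch", seq_len(n_channels))
  cfg <- list(
    n_channels = n_channels, rate = rate, channels = channels,
    artifact_gain_slight = artifact_gain_slight,
    artifact_gain_regular = artifact_gain_regular,
    background_order = background_order,
    noise_sd = noise_sd, pink_sd = pink_sd,
    osc_amplitude = osc_amplitude, burst_sd = burst_sd,
    seed = as.integer(seed)
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 1L))
  cfg$background <- random_stable_mvar(n_channels, background_order, radius = 0.85)
  # per-channel EMG weighting: concentrated on the facial reference channels
  w <- rep(0.05, n_channels)
  names(w) <- channels
  refs <- intersect(sfe_reference_channels(), channels)
  w[refs] <- c(0.95, 0.9, 0.7, 0.7, 0.55, 0.55)[seq_along(refs)]
  cfg$artifact_channels_weight <- w
  # eight classes: distinct centre frequencies and unit-norm spatial patterns
  centre <- c(9, 13, 17, 21, 25, 29, 35, 41)
  cls <- sfe_classes()
  cfg$class_patterns <- lapply(seq_along(cls), function(i) {
    v <- stats::rnorm(n_channels)
    v <- v / sqrt(sum(v^2))
    tilt <- pmax(0, 1 + 0.5 * stats::rnorm(n_channels))
    list(class = cls[i], centre_hz = centre[i], spatial = v,
         artifact_tilt = tilt / mean(tilt))
  })
  names(cfg$class_patterns) <- cls
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d ch @ %g Hz, gains slight=%g regular=%g, seed=%d\n",
              x$n_channels, x$rate, x$artifact_gain_slight,
              x$artifact_gain_regular, x$seed))
  invisible(x)
}

# counter-based seed split; stays below 2^31
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 9973) %% 2147483562) + 1L
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Random stable MVAR model
#'
#' Draws coefficient matrices with independent normal entries and rescales
#' them so the companion matrix has the requested spectral radius (< 1,
#' hence stable). Uses the current RNG state.
#'
#' @param ch Number of channels.
#' @param order Model order.
#' @param radius Target spectral radius (default 0.85).
#' @param sd Entry standard deviation before rescaling.
#' @return An `mvar_model` (see [mvar_model()]) with identity noise
#'   covariance.
#' @export
random_stable_mvar <- function(ch, order, radius = 0.85, sd = 0.15) {
  coeffs <- lapply(seq_len(order), function(r) {
    matrix(stats::rnorm(ch * ch, sd = sd / r), ch, ch)
  })
  rho <- companion_radius(coeffs)
  if (rho > 0) {
    coeffs <- lapply(seq_len(order), function(r) coeffs[[r]] * (radius / rho)^r)
  }
  mvar_model(order = order, coeffs = coeffs, noise_cov = diag(ch))
}

companion_radius <- function(coeffs) {
  ch <- nrow(coeffs[[1]])
  m <- length(coeffs)
  comp <- matrix(0, ch * m, ch * m)
  comp[1:ch, ] <- do.call(cbind, coeffs)
  if (m > 1) {
    comp[(ch + 1):(ch * m), 1:(ch * (m - 1))] <- diag(ch * (m - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Simulate an MVAR process with the current RNG state.
mvar_sim <- function(model, n, burn_in = 500, innovation_sd = 1) {
  ch <- nrow(model$coeffs[[1]])
  m <- model$order
  A <- do.call(cbind, model$coeffs)        # ch x (ch*m), lag 1..m blocks
  L <- t(chol(model$noise_cov))
  total <- n + burn_in
  w <- L %*% matrix(stats::rnorm(ch * total, sd = innovation_sd), ch, total)
  y <- matrix(0, ch, total)
  y[, 1:m] <- w[, 1:m]
  for (t in (m + 1):total) {
    past <- y[, t - seq_len(m), drop = FALSE]   # lag 1..m as columns
    y[, t] <- A %*% as.vector(past) + w[, t]
  }
  y[, (burn_in + 1):total, drop = FALSE]
}

# 1/f^2-power-shaped noise (steep EEG-like spectral fall-off), one
# channel x n matrix, current RNG state.
pink_noise <- function(ch, n, sd) {
  out <- matrix(0, ch, n)
  f <- c(1, seq_len(floor(n / 2)))           # guard DC
  for (i in seq_len(ch)) {
    spec <- stats::rnorm(n) + 1i * stats::rnorm(n)
    shape <- numeric(n)
    half <- floor(n / 2)
    shape[1:(half + 1)] <- 1 / f[1:(half + 1)]
    if (half > 1) shape[(n - half + 2):n] <- rev(shape[2:half])
    x <- Re(stats::fft(spec * shape, inverse = TRUE))
    out[i, ] <- x / stats::sd(x) * sd
  }
  out
}

# Background segment: rhythm-band MVAR (low-passed to the sub-30 Hz range
# where resting EEG rhythms live) plus steep 1/f noise.
synth_background <- function(cfg, n) {
  bg <- mvar_sim(cfg$background, n, burn_in = 300, innovation_sd = cfg$noise_sd)
  lp <- signal::butter(4, 30 / (cfg$rate / 2), type = "low")
  for (i in seq_len(nrow(bg))) bg[i, ] <- signal::filtfilt(lp, bg[i, ])
  bg + pink_noise(cfg$n_channels, n, cfg$pink_sd)
}

# EMG-like burst source: broadband noise whose spectrum rises toward the
# 55-95 Hz band (dominant, as facial-EMG spectra do) with a weaker 20-55 Hz
# component leaking into the decoding band; 150 ms raised-cosine rise/fall
# envelope and slow amplitude modulation.
synth_burst <- function(cfg, n) {
  hi <- signal::butter(4, c(55, 95) / (cfg$rate / 2), type = "pass")
  lo <- signal::butter(4, c(20, 55) / (cfg$rate / 2), type = "pass")
  s_hi <- signal::filtfilt(hi, stats::rnorm(n, sd = 1))
  s_lo <- signal::filtfilt(lo, stats::rnorm(n, sd = 1))
  src <- s_hi / stats::sd(s_hi) + 0.15 * s_lo / stats::sd(s_lo)
  src <- src / stats::sd(src) * cfg$burst_sd
  rise <- round(0.15 * cfg$rate)
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(rise) / rise))
  env[1:rise] <- ramp
  env[(n - rise + 1):n] <- rev(ramp)
  slow <- 1 + 0.2 * sin(2 * pi * 1.1 * seq_len(n) / cfg$rate + stats::runif(1, 0, 2 * pi))
  src * env * slow
}

# Narrow-band class oscillation projected through the class spatial pattern.
synth_oscillation <- function(cfg, pattern, n) {
  t <- seq_len(n) / cfg$rate
  phase <- stats::runif(1, 0, 2 * pi)
  am <- 1 + 0.3 * sin(2 * pi * 0.9 * t + stats::runif(1, 0, 2 * pi))
  carrier <- sin(2 * pi * pattern$centre_hz * t + phase) +
    0.4 * sin(2 * pi * (pattern$centre_hz * 1.9) * t + stats::runif(1, 0, 2 * pi))
  outer(pattern$spatial, cfg$osc_amplitude * am * carrier)
}

#' Trial plan
#'
#' Segment durations of one trial: countdown, resting, sFE and relaxing
#' state, in seconds, plus the target class.
#'
#' @param class One of [sfe_classes()].
#' @param countdown,rest,sfe,relax Segment durations in seconds.
#' @return A `trial_plan` list.
#' @export
trial_plan <- function(class, countdown = 3, rest = 4, sfe = 4, relax = 4) {
  if (!class %in% sfe_classes()) {
    stop(sprintf("invalid class '%s'", class), call. = FALSE)
  }
  structure(list(class = class, countdown = countdown, rest = rest,
                 sfe = sfe, relax = relax),
            class = "trial_plan")
}

#' Generate one annotated synthetic trial
#'
#' Segments follow the trial timing (countdown, rest, sFE, relax). The rest
#' segment carries background only; the sFE segment adds the class
#' oscillation plus an EMG-like burst weighted onto the facial reference
#' channels and scaled by the intensity gain; the relax segment adds random
#' low-frequency frontal transients.
#'
#' @param plan A [trial_plan()].
#' @param cfg A [synth_config()].
#' @param intensity `"slight"` or `"regular"`.
#' @param seed Seed for this trial (default: derived from `cfg$seed`).
#' @return An `eeg_recording` with annotations `countdown`, `rest`,
#'   `sfe:<class>` (or `regularFE:<class>`) and `relax`.
#' @export
generate_trial <- function(plan, cfg, intensity = c("slight", "regular"),
                           seed = derive_seed(cfg$seed, 2L)) {
  intensity <- match.arg(intensity)
  pattern <- cfg$class_patterns[[plan$class]]
  if (is.null(pattern)) stop(sprintf("invalid class '%s'", plan$class), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  durs <- c(countdown = plan$countdown, rest = plan$rest,
            sfe = plan$sfe, relax = plan$relax)
  ns <- round(durs * cfg$rate)
  total <- sum(ns)
  x <- synth_background(cfg, total)

  # sFE segment: class oscillation + weighted EMG burst
  gain <- switch(intensity, slight = cfg$artifact_gain_slight,
                 regular = cfg$artifact_gain_regular)
  i_sfe <- (ns[1] + ns[2] + 1):(ns[1] + ns[2] + ns[3])
  x[, i_sfe] <- x[, i_sfe] + synth_oscillation(cfg, pattern, ns[3])
  burst <- synth_burst(cfg, ns[3])
  w <- cfg$artifact_channels_weight * pattern$artifact_tilt
  x[, i_sfe] <- x[, i_sfe] + gain * outer(unname(w), burst)

  # relax segment: low-frequency frontal transients
  i_rel <- (total - ns[4] + 1):total
  front <- match(intersect(c("Fp1", "Fp2", "F7", "F8"), cfg$channels), cfg$channels)
  n_tr <- if (plan$relax >= 0.5 && length(front)) stats::rpois(1, 3) + 1 else 0
  t_rel <- seq_len(ns[4])
  for (k in seq_len(n_tr)) {
    c0 <- stats::runif(1, 0.1, plan$relax - 0.1) * cfg$rate
    width <- stats::runif(1, 0.1, 0.4) * cfg$rate
    bump <- 25 * exp(-((t_rel - c0)^2) / (2 * width^2))
    ch <- sample(front, 1)
    x[ch, i_rel] <- x[ch, i_rel] + bump * sign(stats::rnorm(1))
  }

  lab_sfe <- if (intensity == "slight") paste0("sfe:", plan$class)
             else paste0("regularFE:", plan$class)
  bounds <- cumsum(c(0, durs))
  ann <- data.frame(
    start = unname(bounds[1:4]), end = unname(bounds[2:5]),
    label = c("countdown", "rest", lab_sfe, "relax"),
    row.names = NULL
  )
  eeg_recording(x, cfg$rate, cfg$channels, ann)
}

#' Generate an annotated multi-trial session
#'
#' Concatenates trials in a randomized (seeded) class order; each trial uses
#' its own counter-derived random stream so sessions are reproducible.
#'
#' @param classes Character vector of sFE classes to include.
#' @param trials_per_class Trials per class (>= 1).
#' @param cfg A [synth_config()].
#' @param intensity `"slight"` or `"regular"`.
#' @param seed Session seed (default `cfg$seed`).
#' @return An `eeg_recording` with per-segment annotations over the whole
#'   session.
#' @export
generate_session <- function(classes, trials_per_class, cfg,
                             intensity = "slight", seed = cfg$seed) {
  if (length(classes) == 0) stop("invalid input: empty class list", call. = FALSE)
  stopifnot(trials_per_class >= 1)
  bad <- setdiff(classes, sfe_classes())
  if (length(bad)) stop(sprintf("invalid class '%s'", bad[1]), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L))
  order_cls <- sample(rep(classes, trials_per_class))
  parts <- vector("list", length(order_cls))
  anns <- vector("list", length(order_cls))
  offset <- 0
  for (i in seq_along(order_cls)) {
    tr <- generate_trial(trial_plan(order_cls[i]), cfg, intensity,
                         seed = derive_seed(seed, 100L + i))
    parts[[i]] <- tr$data
    a <- tr$annotations
    a$start <- a$start + offset
    a$end <- a$end + offset
    anns[[i]] <- a
    offset <- offset + rec_duration(tr)
  }
  eeg_recording(do.call(cbind, parts), cfg$rate, cfg$channels,
                do.call(rbind, anns))
}

#' Simulate a known MVAR process
#'
#' Oracle input for the connectivity estimators: a realization of a fully
#' specified MVAR model with unit-variance Gaussian innovations (unless the
#' model's noise covariance says otherwise).
#'
#' @param model An [mvar_model()] (must be stable).
#' @param n_samples Number of samples to return (after burn-in).
#' @param seed Integer seed.
#' @param burn_in Discarded leading samples (default 500).
#' @return An `eeg_recording` at a nominal rate of 1000 Hz.
#' @export
generate_known_mvar <- function(model, n_samples, seed, burn_in = 500) {
  if (companion_radius(model$coeffs) >= 1) {
    stop("model is unstable (spectral radius >= 1)", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  y <- mvar_sim(model, n_samples, burn_in = burn_in)
  eeg_recording(y, 1000, paste0("ch", seq_len(nrow(y))))
}
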