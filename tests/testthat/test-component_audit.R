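emd_first_imf <- function(v) {
  decompose(matrix(v, 1, length(v)), "NA-MEMD")$imfs[[1]][1, ]
}

# Brute-force O(N^2) template-counting oracle for sample entropy,
# independent of the vectorized implementation.
sampen_oracle <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * sd(x)
  count <- function(len) {
    nt <- n - m
    hits <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) {
          hits <- hits + 1
        }
      }
    }
    hits
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

test_that("sample entropy equals the brute-force oracle on seeded sequences", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(20:200, 1)
    x <- runif(n)
    expect_identical(sample_entropy(x), sampen_oracle(x), label = paste("seed", s))
  }
})

test_that("sample entropy handles degenerate input and orders regularity", {
  expect_equal(sample_entropy(rep(3.2, 100)), 0)
  expect_error(sample_entropy(c(1, 2, 3)), "too short")
  set.seed(10)
  noise <- rnorm(1000)
  sine <- sin(2 * pi * 10 * seq_len(1000) / 1000)
  expect_gt(sample_entropy(noise), sample_entropy(sine))
  expect_gt(sample_entropy(noise), 0.45)   # EMG-like irregularity
  expect_lt(sample_entropy(sine), 0.45)    # rhythmic EEG-like component
})

test_that("FastICA unmixes known sources and rejects single channels", {
  set.seed(4)
  t <- seq_len(3000) / 1000
  s1 <- sin(2 * pi * 7 * t)
  s2 <- sign(sin(2 * pi * 13 * t + 1))     # non-Gaussian square wave
  A <- matrix(c(1, 0.4, 0.6, 1), 2, 2)
  x <- A %*% rbind(s1, s2)
  for (contrast in c("tanh", "gauss")) {
    cs <- decompose(eeg_recording(x, 1000, c("a", "b")), "fastICA",
                    contrast = contrast, seed = 2)
    cors <- abs(cor(t(cs$components), cbind(s1, s2)))
    expect_gt(max(cors[, 1]), 0.95)
    expect_gt(max(cors[, 2]), 0.95)
    # mixing %*% components reconstructs the input
    back <- cs$mixing %*% cs$components + cs$center
    expect_lt(max(abs(back - x)), 1e-6)
  }
  expect_error(decompose(eeg_recording(matrix(rnorm(100), 1, 100), 1000, "a"),
                         "fastICA"), "at least 2 channels")
})

test_that("EMD separates well-spaced tones into distinct modes", {
  t <- seq_len(2000) / 1000
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
  cs <- decompose(eeg_recording(matrix(x, 1, 2000), 1000, "a"), "NA-MEMD")
  imfs <- cs$imfs[[1]]
  expect_gte(nrow(imfs), 3)                # two tones + residue
  peak_hz <- function(v) {
    sp <- Mod(fft(v))[2:1000]
    which.max(sp) * 1000 / 2000
  }
  peaks <- apply(imfs[1:2, ], 1, peak_hz)
  expect_lt(abs(peaks[1] - 40), 3)         # fastest mode first
  expect_lt(abs(peaks[2] - 5), 2)
  # sifting is additive: modes plus residue reproduce the signal
  expect_lt(max(abs(colSums(imfs) - x)), 1e-9)
})

test_that("component labeling follows the entropy threshold strictly", {
  set.seed(6)
  seqs <- rbind(rnorm(400), sin(2 * pi * 8 * seq_len(400) / 1000))
  cs <- structure(list(method = "fastICA", components = seqs,
                       mixing = diag(2), center = c(0, 0),
                       channels = c("a", "b"), rate = 1000),
                  class = "component_set")
  expect_equal(unname(label_components(cs)), c("EMG", "EEG"))
  se <- sample_entropy(seqs[2, ])
  # boundary: strictly above the threshold means EMG, at/below means EEG
  expect_equal(unname(label_components(cs, entropy_params(threshold = se))[2]),
               "EEG")
  expect_equal(unname(label_components(cs, entropy_params(threshold = se - 1e-9))[2]),
               "EMG")
})

test_that("clean reconstruction keeps EEG components and drops EMG ones", {
  t <- seq_len(1500) / 1000
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
  rec <- eeg_recording(matrix(x, 1, 1500), 1000, "a")
  cs <- decompose(rec, "NA-MEMD")
  k <- nrow(cs$imfs[[1]])

  all_eeg <- reconstruct_clean(cs, list(rep("EEG", k)))
  expect_lt(max(abs(all_eeg$data - x)), 1e-9)

  all_emg <- reconstruct_clean(cs, list(rep("EMG", k)))
  expect_equal(max(abs(all_emg$data)), 0)

  drop1 <- reconstruct_clean(cs, list(c("EMG", rep("EEG", k - 1))))
  expect_lt(max(abs(drop1$data - (x - cs$imfs[[1]][1, ]))), 1e-9)
})

test_that("energy reduction ratio is exact and scale invariant", {
  rec <- eeg_recording(tiny_window(9, 3, 200), 1000)
  expect_true(all(energy_reduction_ratio(rec, rec) == 0))
  zero <- eeg_recording(matrix(0, 3, 200), 1000, rec$channels)
  expect_true(all(energy_reduction_ratio(rec, zero) == 100))
  half <- eeg_recording(rec$data / sqrt(2), 1000, rec$channels)
  expect_equal(unname(energy_reduction_ratio(rec, half)), rep(50, 3))
  scaled <- energy_reduction_ratio(
    eeg_recording(rec$data * 3, 1000, rec$channels),
    eeg_recording(half$data * 3, 1000, rec$channels))
  expect_equal(unname(scaled), rep(50, 3))
})

test_that("entropy rises with the band and flags wide-band EMG content", {
  cfg <- default_cfg()
  wide_above <- 0
  ordered <- 0
  rhythm_below <- 0
  n_trials <- 6
  for (s in seq_len(n_trials)) {
    slight <- generate_trial(trial_plan(sfe_classes()[s]), cfg, "slight",
                             seed = 700 + s)
    regular <- generate_trial(trial_plan(sfe_classes()[s]), cfg, "regular",
                              seed = 700 + s)
    narrow <- bandpass(rec_slice(slight, 7.5, 9.5), band_spec(5, 50))
    wide <- bandpass(rec_slice(regular, 7.5, 9.5), band_spec(5, 95))
    se_wide <- sample_entropy(wide$data["Fp1", ])
    se_narrow <- sample_entropy(narrow$data["Fp1", ])
    # sub-30 Hz resting rhythms are the regular (EEG-like) part
    rhythms <- bandpass(rec_slice(slight, 3.5, 5.5), band_spec(5, 30))
    if (se_wide > 0.45) wide_above <- wide_above + 1
    if (se_wide > se_narrow) ordered <- ordered + 1
    if (sample_entropy(rhythms$data["Fp1", ]) <= 0.45) {
      rhythm_below <- rhythm_below + 1
    }
  }
  expect_gte(wide_above / n_trials, 0.9)
  expect_gte(ordered / n_trials, 0.9)
  expect_gte(rhythm_below / n_trials, 0.9)
})
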