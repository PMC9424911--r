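test_that("recording construction enforces its invariants", {
  m <- tiny_window(1, ch = 3, n = 50)
  rec <- eeg_recording(m, 1000)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(rec$channels, rownames(m))
  expect_error(eeg_recording(m, 1000, channels = c("a", "a", "b")), "unique")
  expect_error(eeg_recording(m, -1), "rate")
  m[1, 1] <- NA
  expect_error(eeg_recording(m, 1000), "finite")
  expect_error(
    eeg_recording(tiny_window(1, 3, 50), 1000,
                  annotations = data.frame(start = 1, end = 0.5, label = "rest")),
    "start < end")
})

test_that("bandpass attenuates out-of-band and passes in-band sinusoids", {
  zero <- eeg_recording(matrix(0, 2, 1000), 1000, c("a", "b"))
  expect_equal(max(abs(bandpass(zero, band_spec(5, 50))$data)), 0)

  # steady-state attenuation must match the filter's analytic frequency
  # response (|H(f)|^2 for forward-backward application)
  bf <- signal::butter(4, c(5, 50) / 500, type = "pass")
  gain2 <- function(f_hz) {
    w <- 2 * pi * f_hz / 1000
    zb <- exp(-1i * w * (seq_along(bf$b) - 1))
    za <- exp(-1i * w * (seq_along(bf$a) - 1))
    Mod(sum(bf$b * zb) / sum(bf$a * za))^2
  }
  rms <- function(x) sqrt(mean(x^2))
  interior <- 1000:3000

  s70 <- sine_recording(70, dur = 4)
  out70 <- bandpass(s70, band_spec(5, 50))
  ratio70 <- rms(out70$data[1, interior]) / rms(s70$data)
  expect_lt(ratio70, 0.05)
  expect_lt(abs(ratio70 - gain2(70)) / gain2(70), 0.2)

  s20 <- sine_recording(20, dur = 4)
  out20 <- bandpass(s20, band_spec(5, 50))
  ratio20 <- rms(out20$data[1, interior]) / rms(s20$data)
  expect_lt(abs(ratio20 - 1), 0.1)
  expect_lt(abs(ratio20 - gain2(20)) / gain2(20), 0.05)

  expect_error(bandpass(s20, band_spec(5, 600)), "Nyquist")
})

test_that("bandpass is zero-phase and idempotent within tolerance", {
  s20 <- sine_recording(20)
  once <- bandpass(s20, band_spec(5, 50))
  twice <- bandpass(once, band_spec(5, 50))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(twice$data) / rms(once$data) - 1), 0.01)
  # zero phase: peak of the in-band sinusoid stays aligned (interior sample)
  mid <- 500:1500
  expect_lt(max(abs(once$data[1, mid] - s20$data[1, mid])) / 10, 0.12)
})

test_that("slice_windows counts, ordering and tiling are exact", {
  rec <- eeg_recording(matrix(seq_len(400), 1, 400), 1000, "a")
  expect_length(slice_windows(rec, 100, 100), 4)
  expect_length(slice_windows(rec, 100, 50), 7)
  short <- eeg_recording(matrix(0, 1, 99), 1000, "a")
  expect_length(slice_windows(short, 100, 10), 0)
  # tiling reproduces the leading samples exactly
  tiles <- slice_windows(rec, 100, 100)
  expect_equal(as.numeric(do.call(cbind, lapply(tiles, unclass))),
               as.numeric(rec$data[, 1:400]))
  starts <- vapply(tiles, function(w) attr(w, "start"), 1L)
  expect_equal(starts, c(0L, 100L, 200L, 300L))
})

test_that("temporal energy matches brute force and scales quadratically", {
  expect_equal(temporal_energy(rep(0, 10)), 0)
  expect_equal(temporal_energy(c(1, 2, 3)), 14)
  expect_error(temporal_energy(numeric(0)), "empty")
  set.seed(42)
  x <- rnorm(100)
  brute <- 0
  for (v in x) brute <- brute + v * v
  expect_equal(temporal_energy(x), brute)
  expect_equal(temporal_energy(sample(x)), temporal_energy(x))
  expect_equal(temporal_energy(3 * x), 9 * temporal_energy(x))
})

test_that("downsample preserves duration, DC and spectral peaks", {
  rec <- eeg_recording(matrix(rnorm(4000), 1, 4000), 1000, "a")
  out <- downsample(rec, 512)
  expect_equal(out$rate, 512)
  expect_lte(abs(ncol(out$data) - 2048), 1)

  const <- eeg_recording(matrix(5, 1, 2000), 1000, "a")
  dc <- downsample(const, 512)
  expect_lt(max(abs(dc$data - 5)), 1e-6)

  s10 <- sine_recording(10, dur = 4)
  ds <- downsample(s10, 512)
  spec <- Mod(fft(ds$data[1, ]))[2:(ncol(ds$data) / 2)]
  peak_hz <- which.max(spec) * 512 / ncol(ds$data)
  expect_lt(abs(peak_hz - 10), 0.5)

  expect_error(downsample(rec, 2000), "target_rate")
})

test_that("CSV round trip preserves data, rate and channel names", {
  rec <- eeg_recording(tiny_window(3, 5, 200), 500,
                       annotations = data.frame(start = 0, end = 0.1,
                                                label = "rest"))
  path <- tempfile(fileext = ".csv")
  ann <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path, ann)
  back <- read_recording_csv(path, ann)
  expect_lt(max(abs(back$data - rec$data)), 1e-6)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$rate, rec$rate)
  expect_equal(back$annotations$label, "rest")
  expect_error(read_recording_csv(path, expected_channels = sfe_montage()),
               "montage mismatch")
})

test_that("EDF round trip reproduces a 30-channel recording", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(30 * 2000, sd = 20), 30, 2000), 1000,
                       sfe_montage())
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$channels, sfe_montage())
  expect_equal(back$rate, 1000)
  # 16-bit quantization over ~ +-100 uV range
  expect_lt(max(abs(back$data - rec$data)), 0.01)

  # montage order normalized even when the file is shuffled
  shuffled <- eeg_recording(rec$data[rev(seq_len(30)), ], 1000,
                            rev(sfe_montage()))
  write_edf(shuffled, path)
  back2 <- read_edf(path)
  expect_equal(back2$channels, sfe_montage())
  expect_lt(max(abs(back2$data - rec$data)), 0.01)

  # 29 channels is a montage mismatch
  write_edf(eeg_recording(rec$data[1:29, ], 1000, sfe_montage()[1:29]), path)
  expect_error(read_edf(path), "montage mismatch")
})
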