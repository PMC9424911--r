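test_that("fit_mvar recovers known coefficients and flags degenerate input", {
  set.seed(2)
  wn <- matrix(rnorm(2 * 20000), 2, 20000)
  null_fit <- fit_mvar(wn, 2)
  expect_true(all(abs(unlist(null_fit$coeffs)) < 0.05))

  A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  rec <- generate_known_mvar(mvar_model(1, list(A1), diag(2)), 20000, seed = 3)
  fit <- fit_mvar(rec$data, 1)
  expect_true(all(abs(fit$coeffs[[1]] - A1) < 0.05))
  expect_true(all(abs(fit$noise_cov - diag(2)) < 0.1))

  expect_error(fit_mvar(matrix(rnorm(20), 2, 10), 3), "singular fit")
})

test_that("AIC order selection finds the true order", {
  expect_equal(select_order(matrix(rnorm(2000), 2, 1000), orders = 3), 3)

  set.seed(14)
  true3 <- random_stable_mvar(3, 3, radius = 0.8)
  hits3 <- sum(vapply(1:10, function(s) {
    r <- generate_known_mvar(true3, 20000, seed = 100 + s)
    select_order(r$data, max_order = 10) == 3
  }, logical(1)))
  expect_gte(hits3, 8)

  hits_wn <- sum(vapply(1:10, function(s) {
    set.seed(200 + s)
    select_order(matrix(rnorm(3 * 20000), 3, 20000), max_order = 6) == 1
  }, logical(1)))
  expect_gte(hits_wn, 8)
})

test_that("spectral transform matches its closed form and a direct-sum oracle", {
  zero <- mvar_model(2, list(matrix(0, 3, 3), matrix(0, 3, 3)), diag(3))
  S <- spectral_matrix(zero, c(1, 100, 400))
  for (k in 1:3) expect_equal(S[, , k], diag(3) + 0i)

  ar1 <- mvar_model(1, list(matrix(0.5, 1, 1)), diag(1))
  S0 <- spectral_matrix(ar1, 1e-6)
  expect_equal(Re(S0[1, 1, 1]), 0.5, tolerance = 1e-6)

  set.seed(8)
  mod <- random_stable_mvar(3, 2, radius = 0.7)
  freqs <- c(7, 33, 210)
  S2 <- spectral_matrix(mod, freqs)
  for (k in seq_along(freqs)) {               # independent direct evaluation
    expected <- diag(3)
    for (r in 1:2) {
      expected <- expected - mod$coeffs[[r]] * exp(-2i * pi * freqs[k] * r / 1000)
    }
    expect_equal(S2[, , k], expected)
  }
})

test_that("gOPDC vanishes without coupling and detects direction", {
  un <- mvar_model(1, list(diag(c(0.5, 0.3))), diag(2))
  gu <- gopdc(un, freqs = seq(10, 490, by = 40))
  expect_true(all(gu[1, 2, ] == 0))
  expect_true(all(gu[2, 1, ] == 0))
  expect_true(all(is.nan(gu[1, 1, ])))

  A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  uni <- mvar_model(1, list(A1), diag(2))
  g <- gopdc(uni, freqs = seq(1, 499, by = 2))
  expect_gt(mean(g[2, 1, ]), 10 * mean(g[1, 2, ]))

  # lag-2-only coupling is purely real at a quarter of the sampling rate
  lag2 <- mvar_model(2, list(matrix(0, 2, 2), matrix(c(0.4, 0.3, 0, 0.4), 2, 2)),
                     diag(2))
  g2 <- gopdc(lag2, freqs = 250)
  expect_equal(g2[2, 1, 1], 0)
})

test_that("gOPDC is permutation-consistent and scale-robust in direction", {
  set.seed(21)
  mod <- random_stable_mvar(3, 2, radius = 0.7)
  freqs <- seq(5, 495, by = 10)
  g <- gopdc(mod, freqs)
  perm <- c(3, 1, 2)
  pmod <- mvar_model(2, lapply(mod$coeffs, function(A) A[perm, perm]),
                     mod$noise_cov[perm, perm])
  gp <- gopdc(pmod, freqs)
  expect_equal(gp, structure(g[perm, perm, ], freqs = freqs,
                             class = c("gopdc_map", "array")),
               ignore_attr = TRUE)

  # scaling one channel's signal preserves which direction dominates
  A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  rec <- generate_known_mvar(mvar_model(1, list(A1), diag(2)), 20000, seed = 9)
  scaled <- rec$data
  scaled[1, ] <- scaled[1, ] * 7
  for (dat in list(rec$data, scaled)) {
    fit <- fit_mvar(dat, 1)
    gg <- gopdc(fit, freqs = seq(1, 499, by = 5))
    expect_gt(mean(gg[2, 1, ]), mean(gg[1, 2, ]))
  }
})

test_that("sliding gOPDC tracks stationarity and change points", {
  A1 <- matrix(c(0.5, 0.45, 0, 0.5), 2, 2)
  uni <- mvar_model(1, list(A1), diag(2))
  un <- mvar_model(1, list(diag(c(0.5, 0.5))), diag(2))

  stat_rec <- generate_known_mvar(uni, 4000, seed = 41)
  sl <- sliding_gopdc(stat_rec, win_s = 0.5, step_s = 0.5, order = 1,
                      freqs = seq(5, 495, by = 10))
  expect_length(sl$maps, 8)
  flows <- vapply(sl$maps, function(m) mean(m[2, 1, ]), numeric(1))
  expect_lt(sd(flows) / mean(flows), 0.5)

  hits <- sum(vapply(1:10, function(s) {
    pre <- generate_known_mvar(un, 2000, seed = 500 + s)
    post <- generate_known_mvar(uni, 2000, seed = 600 + s)
    rec <- eeg_recording(cbind(pre$data, post$data), 1000, c("ch1", "ch2"))
    sw <- sliding_gopdc(rec, win_s = 0.5, step_s = 0.5, order = 1,
                        freqs = seq(5, 495, by = 10))
    f <- vapply(sw$maps, function(m) mean(m[2, 1, ]), numeric(1))
    mean(f[5:8]) > mean(f[1:4])
  }, logical(1)))
  expect_gte(hits, 8)

  one <- sliding_gopdc(stat_rec, win_s = 0.5, step_s = 4, order = 1,
                       freqs = c(10, 20))
  expect_length(one$maps, 8 - 7)              # step = record length: 1 window
})

test_that("band averaging and baseline thresholding behave as order statistics", {
  m <- array(0.25, dim = c(2, 2, 50))
  map <- structure(m, freqs = 1:50, class = c("gopdc_map", "array"))
  ba <- band_average(map)
  expect_length(ba, 3)
  expect_true(all(vapply(ba, function(x) all(x == 0.25), logical(1))))

  two <- structure(array(c(1, 2, 3, 4, 5, 6, 7, 8), dim = c(2, 2, 2)),
                   freqs = c(6, 10), class = c("gopdc_map", "array"))
  avg <- band_average(two, bands = list(low = c(4, 12)))$low
  expect_equal(avg, matrix(c(3, 4, 5, 6), 2, 2))

  expect_equal(baseline_threshold(matrix(1:100, 10, 10), percentile = 99), 99)
  masked <- apply_threshold(matrix(1:100, 10, 10), 99)
  expect_equal(sum(!is.na(masked)), 1)
  expect_equal(masked[100], 100)
  all_blocked <- apply_threshold(matrix(1:4, 2, 2), 10)
  expect_true(all(is.na(all_blocked)))

  # null simulation: about 1% of entries survive the 99th-percentile mask
  set.seed(77)
  null_maps <- lapply(1:5, function(i) {
    rec <- matrix(rnorm(3 * 3000), 3, 3000)
    gopdc(fit_mvar(rec, 2), freqs = seq(5, 495, by = 10))
  })
  thr <- baseline_threshold(null_maps, 99)
  vals <- unlist(lapply(null_maps, function(m) m[is.finite(m)]))
  expect_lt(abs(mean(vals > thr) - 0.01), 0.005)
})
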