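test_that("screening thresholds are 105% of the per-channel training maxima", {
  w <- matrix(0.1, 30, 100, dimnames = list(sfe_montage(), NULL))
  w["Fp1", ] <- sqrt(2)                  # energy 100 * 2 = 200
  bank <- fit_step_a(list(w))
  expect_equal(unname(unclass(bank)[["Fp1"]]), 210)

  set.seed(12)
  windows <- lapply(1:25, function(i) tiny_window(i))
  bank2 <- fit_step_a(windows)
  brute <- sapply(sfe_reference_channels(), function(ch) {
    1.05 * max(sapply(windows, function(w) sum(w[ch, ]^2)))
  })
  expect_equal(unclass(bank2), brute, ignore_attr = TRUE)
  # every training window is re-accepted (threshold strictly above max)
  expect_true(all(vapply(windows, step_a_screen, "", bank = bank2) == "accept"))

  no_fp1 <- matrix(0, 29, 100, dimnames = list(sfe_montage()[-1], NULL))
  expect_error(fit_step_a(list(no_fp1)), "montage mismatch")
})

test_that("screening accepts zeros and boundary windows, rejects exceedance", {
  set.seed(3)
  w_max <- tiny_window(99)
  bank <- fit_step_a(list(w_max))
  zero <- matrix(0, 30, 100, dimnames = list(sfe_montage(), NULL))
  expect_equal(step_a_screen(zero, bank), "accept")
  expect_equal(step_a_screen(w_max, bank), "accept")   # energy = max < 1.05 max
  hot <- w_max
  hot["F7", ] <- hot["F7", ] * 1.2                     # energy x1.44 > 1.05
  expect_equal(step_a_screen(hot, bank), "reject")
})

test_that("the threshold-method score reproduces the printed comparisons", {
  expect_equal(round_half_up(threshold_method_score(0.9945, 0.6866, 0.0055)),
               40.53)
  expect_equal(round_half_up(threshold_method_score(0.9948, 0.6467, 0.0055)),
               39.11)
  expect_equal(threshold_method_score(1, 1, 0), 50)
})

test_that("CSP features follow the log-variance ratio construction", {
  v <- sin(seq_len(100) / 5) * 3
  w4 <- rbind(v, v, v, v)
  model <- structure(list(filters = diag(4), pairs = 2), class = "csp_model")
  f <- csp_features(model, w4)
  expect_equal(unname(f), rep(0.25, 4))

  set.seed(8)
  win <- tiny_window(21, ch = 4, n = 100)
  f2 <- csp_features(model, win)
  expect_equal(sum(f2), 1)

  const <- matrix(1, 4, 100)               # zero variance -> degenerate
  expect_error(csp_features(model, const), "degenerate")
})

test_that("fitted CSP matches a generalized-eigenproblem oracle and separates", {
  set.seed(31)
  mk <- function(boost, n) {
    lapply(seq_len(n), function(i) {
      w <- matrix(rnorm(4 * 200), 4, 200)
      w[2, ] <- w[2, ] * boost
      rownames(w) <- paste0("ch", 1:4)
      w
    })
  }
  wa <- mk(3, 40)
  wb <- mk(1, 40)
  model <- fit_csp(wa, wb, pairs = 2)
  expect_equal(dim(model$filters), c(4, 4))

  # independent oracle: eigenvectors of solve(C1 + C2) %*% C1
  C1 <- sfebci:::mean_normalized_cov(wa)
  C2 <- sfebci:::mean_normalized_cov(wb)
  eg <- eigen(solve(C1 + C2) %*% C1)
  oracle_first <- Re(eg$vectors[, 1])
  got <- model$filters[1, ]
  cos_angle <- abs(sum(oracle_first * got)) /
    sqrt(sum(oracle_first^2) * sum(got^2))
  expect_gt(cos_angle, 0.99)

  # the leading feature separates the classes
  fa <- csp_feature_matrix(model, wa)[, 1]
  fb <- csp_feature_matrix(model, wb)[, 1]
  ranks <- rank(c(fa, fb))
  auc <- (sum(ranks[seq_along(fa)]) - length(fa) * (length(fa) + 1) / 2) /
    (length(fa) * length(fb))
  expect_gt(max(auc, 1 - auc), 0.9)
})

test_that("the scaled-Gaussian kernel scale follows its closed form", {
  # a feature matrix with pooled variance exactly 0.25 gives gamma = 1
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  X <- (X - mean(X)) / sd(X) * 0.5        # pooled sd 0.5 -> var 0.25
  expect_equal(kernel_scale(X), 1, tolerance = 1e-12)
})

test_that("switch-on detection reaches high held-out accuracy", {
  models <- trained_models()
  holdout <- fixture("holdout_session", function() {
    generate_session(sfe_classes(), 1, default_cfg(), seed = 4242)
  })
  low <- fixture("holdout_low", function() bandpass(holdout, decoding_band()))
  sb <- collect_windows(low, map_step_b, n_per_label = 150)
  feats <- csp_feature_matrix(models$csp, sb$windows)
  pred <- predict_on(models$detector, feats)
  acc <- mean(pred == sb$labels)
  expect_gte(acc, 0.90)
})

test_that("network shapes follow the architecture table", {
  shp <- sfe_net_shapes()
  expect_equal(shp$shape,
               c("100x30", "98x64", "32x64", "30x128", "128", "64", "32", "9"))
})

test_that("an untrained network still emits a nine-way distribution", {
  net <- structure(list(par = sfebci:::sfe_net_init(30, 9, seed = 5),
                        classes = sfe_labels(), scale = 1, val_acc = NA,
                        history = NULL), class = "sfe_net")
  out <- step_c_decode(net, tiny_window(1))
  expect_length(out$probs, 9)
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_true(out$label %in% sfe_labels())
})

test_that("training demands every class and decodes held-out windows well", {
  expect_error(train_sfe_net(lapply(1:10, tiny_window),
                             rep("s-RB", 10), epochs = 1),
               "invalid dataset")

  models <- trained_models()
  holdout <- fixture("holdout_session", function() {
    generate_session(sfe_classes(), 1, default_cfg(), seed = 4242)
  })
  low <- fixture("holdout_low", function() bandpass(holdout, decoding_band()))
  sc <- collect_windows(low, map_step_c, n_per_label = 100)
  pred <- sfe_net_classify(models$net, sc$windows)
  acc <- mean(pred == sc$labels)
  expect_gte(acc, 0.85)

  # resting streams decode to the hold-on class
  non <- sc$windows[sc$labels == "NON"]
  expect_gte(mean(sfe_net_classify(models$net, non) == "NON"), 0.90)
})

test_that("evaluation metrics match direct counts on hand-built cases", {
  perfect <- classification_metrics(rep(sfe_labels(), 3), rep(sfe_labels(), 3))
  expect_equal(perfect$accuracy, 100)
  expect_true(all(diag(perfect$confusion) == 3))
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0)

  truth <- c(rep("a", 10), rep("b", 8), rep("c", 6))
  pred <- c(rep("a", 8), "b", "c", rep("b", 7), "c", rep("c", 5), "a")
  m <- classification_metrics(truth, pred, classes = c("a", "b", "c"))
  expect_equal(unname(m$confusion["a", ]), c(8, 1, 1))
  expect_equal(m$accuracy, 100 * 20 / 24)
  expect_equal(unname(m$precision["a"]), 100 * 8 / 9)
  expect_equal(unname(m$recall["b"]), 100 * 7 / 8)
  # precision and recall for b are both 7/8, so F1 equals them
  expect_equal(unname(m$f1["b"]), 100 * 7 / 8)
})

test_that("k-fold evaluation produces a coherent confusion matrix", {
  low <- slight_low()
  sc <- collect_windows(low, map_step_c, n_per_label = 40)
  m <- evaluate_sfe_net(sc$windows, sc$labels, k_folds = 2, seed = 5,
                        epochs = 4)
  expect_equal(sum(m$confusion), length(sc$labels))
  expect_equal(as.integer(rowSums(m$confusion)[sfe_labels()]),
               as.integer(table(factor(sc$labels, sfe_labels()))[sfe_labels()]))
  expect_gt(m$accuracy, 100 / 9)           # clearly better than chance
})

test_that("the most accurate expression is assigned the most vital instruction", {
  cm <- matrix(5, 9, 9, dimnames = list(sfe_labels(), sfe_labels()))
  diag(cm) <- c(99, 60, 90, 70, 80, 65, 75, 85, 95)
  m <- structure(list(confusion = cm), class = "classification_metrics")
  assign <- assign_instructions(m)
  expect_equal(names(assign)[1], "s-LS")   # highest non-s-RB diagonal
  expect_equal(unname(assign["s-LS"]), "Open")
  expect_false("s-RB" %in% names(assign))
})
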