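#' Confusion matrix and derived metrics
#'
#' @param truth,predicted Character vectors of labels.
#' @param classes Label order (default [sfe_labels()]).
#' @return A `classification_metrics` list: `confusion` (rows = truth,
#'   columns = predicted, counts), `accuracy`, per-class `precision`,
#'   `recall`, `f1` (percent).
#' @export
classification_metrics <- function(truth, predicted, classes = sfe_labels()) {
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  cm <- table(truth = truth, predicted = predicted)
  tp <- diag(cm)
  precision <- 100 * tp / pmax(colSums(cm), 1)
  recall <- 100 * tp / pmax(rowSums(cm), 1)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = unclass(cm),
                 accuracy = 100 * sum(tp) / sum(cm),
                 precision = precision, recall = recall, f1 = f1),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("<classification_metrics> accuracy %.2f%% over %d cases\n",
              x$accuracy, sum(x$confusion)))
  invisible(x)
}

#' Row-normalized confusion matrix in percent
#' @param metrics A `classification_metrics`.
#' @return Matrix of row percentages.
#' @export
confusion_percent <- function(metrics) {
  cm <- metrics$confusion
  100 * cm / pmax(rowSums(cm), 1)
}

#' k-fold cross-validated evaluation of the window classifier
#'
#' Stratified folds; each fold trains a fresh network on the remaining
#' folds and predicts the held-out windows.
#'
#' @param windows List of decoding-band windows.
#' @param labels Character labels.
#' @param k_folds Number of folds (default 10).
#' @param seed Seed for fold assignment and training.
#' @param ... Passed to [train_sfe_net()] (e.g. `epochs`).
#' @return A `classification_metrics` over all out-of-fold predictions.
#' @export
evaluate_sfe_net <- function(windows, labels, k_folds = 10, seed = 1L, ...) {
  labels <- as.character(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 11L))
  fold <- integer(length(labels))
  for (ix in split(seq_along(labels), labels)) {
    fold[ix] <- sample(rep(seq_len(k_folds), length.out = length(ix)))
  }
  pred <- character(length(labels))
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    model <- train_sfe_net(windows[tr], labels[tr],
                           seed = derive_seed(seed, 20L + f), ...)
    pred[te] <- sfe_net_classify(model, windows[te])
  }
  classification_metrics(labels, pred)
}

#' Assign device instructions by decoding accuracy
#'
#' The expression with the highest per-class accuracy (excluding the
#' state-switching class `s-RB`, which is reserved) is mapped to the most
#' vital instruction, the second-most accurate to the second instruction,
#' and so on.
#'
#' @param metrics A `classification_metrics` from validation.
#' @param instructions Instructions ordered from most to least vital.
#' @return Named character vector: instruction per expression class.
#' @export
assign_instructions <- function(metrics,
                                instructions = c("Open", "Left", "Right",
                                                 "Up", "Down", "Backward",
                                                 "Forward")) {
  cp <- confusion_percent(metrics)
  cls <- setdiff(intersect(rownames(cp), sfe_classes()), "s-RB")
  acc <- diag(cp[cls, cls, drop = FALSE])
  names(acc) <- cls
  ranked <- names(sort(acc, decreasing = TRUE))
  n <- min(length(ranked), length(instructions))
  stats::setNames(instructions[seq_len(n)], ranked[seq_len(n)])
}
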