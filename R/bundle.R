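#' Save and load a trained decoder bundle
#'
#' A bundle is a directory of portable text files: YAML metadata (montage,
#' bands, screening thresholds, kernel scale, consistency criteria) plus
#' plain-text weight matrices for the network and CSP filters. The SVM is
#' stored via its support vectors and coefficients and rebuilt on load.
#'
#' @param models A `decoder_models` list from [train_decoder()].
#' @param dir Bundle directory (created if needed).
#' @return `dir`, invisibly; `load_model_bundle` returns a
#'   `decoder_models`.
#' @export
save_model_bundle <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, name) {
    utils::write.table(m, file.path(dir, paste0(name, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  meta <- list(
    montage = sfe_montage(),
    decoding_band = as.numeric(decoding_band()),
    screening_band = as.numeric(screening_band()),
    thresholds = as.list(unclass(models$bank)),
    gamma = models$detector$gamma,
    net_scale = models$net$scale,
    net_classes = models$net$classes,
    net_val_acc = models$net$val_acc,
    csp_pairs = models$csp$pairs
  )
  yaml::write_yaml(meta, file.path(dir, "bundle.yaml"), precision = 15)
  wm(models$csp$filters, "csp_filters")
  for (nm in names(models$net$par)) wm(models$net$par[[nm]], paste0("net_", nm))
  sv <- models$detector$svm
  wm(sv$SV, "svm_sv")
  wm(sv$coefs, "svm_coefs")
  yaml::write_yaml(list(rho = sv$rho,
                        labels = as.character(sv$levels),
                        nSV = as.integer(sv$nSV)),
                   file.path(dir, "svm.yaml"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @param train_fallback Function rebuilding the SVM decision values; not
#'   normally needed.
#' @export
load_model_bundle <- function(dir, train_fallback = NULL) {
  meta <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  rm_ <- function(name) {
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".txt"))))
  }
  bank <- structure(unlist(meta$thresholds), class = "threshold_bank",
                    band = screening_band(), margin = 1.05)
  filters <- rm_("csp_filters")
  dimnames(filters) <- list(paste0("csp", seq_len(nrow(filters))), meta$montage)
  csp <- structure(list(filters = filters, pairs = meta$csp_pairs),
                   class = "csp_model")
  par <- list()
  for (nm in c("W1", "b1", "W2", "b2", "Wx", "bx", "Uz", "Ur", "Uh",
               "Wd1", "bd1", "Wd2", "bd2", "Wd3", "bd3")) {
    m <- rm_(paste0("net_", nm))
    dimnames(m) <- NULL
    if (ncol(m) == 1 && startsWith(nm, "b")) m <- as.numeric(m)
    par[[nm]] <- m
  }
  net <- structure(list(par = par, classes = unlist(meta$net_classes),
                        scale = meta$net_scale, val_acc = meta$net_val_acc,
                        history = NULL), class = "sfe_net")
  svm_meta <- yaml::read_yaml(file.path(dir, "svm.yaml"))
  detector <- structure(
    list(svm = rebuild_svm(rm_("svm_sv"), rm_("svm_coefs"), svm_meta,
                           meta$gamma),
         gamma = meta$gamma),
    class = "on_detector")
  structure(list(bank = bank, csp = csp, detector = detector, net = net),
            class = "decoder_models")
}

# Rebuild a radial-kernel binary SVM decision function from its support
# vectors; returns an object honouring predict() like e1071::svm.
rebuild_svm <- function(SV, coefs, meta, gamma) {
  obj <- list(SV = SV, coefs = as.numeric(coefs), rho = meta$rho,
              labels = meta$labels, gamma = gamma)
  class(obj) <- "sfebci_svm"
  obj
}

#' @export
predict.sfebci_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  # decision value: sum_i coef_i K(sv_i, x) - rho
  d2 <- outer(rowSums(object$SV^2), rowSums(newdata^2), "+") -
    2 * object$SV %*% t(newdata)
  K <- exp(-object$gamma * d2)
  dec <- as.numeric(crossprod(K, object$coefs)) - object$rho
  factor(ifelse(dec >= 0, object$labels[1], object$labels[2]),
         levels = object$labels)
}
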