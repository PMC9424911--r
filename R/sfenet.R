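#' Architecture summary of the nine-class window network
#'
#' The classifier maps one 100-sample x 30-channel window (time-major) to a
#' nine-way distribution: temporal Conv1D (64 filters, kernel 3, stride 1)
#' -> max-pool (3/3, valid) -> temporal Conv1D (128, kernel 3) -> GRU (128
#' units, tanh/sigmoid, last step) -> dense 64 ReLU -> dense 32 ReLU ->
#' dense 9 softmax; categorical cross-entropy, RMSprop (lr 0.001), batch
#' 128.
#'
#' @param input `c(time_steps, channels)`, default `c(100, 30)`.
#' @return Data frame of layer names and output shapes (the shape audit).
#' @export
sfe_net_shapes <- function(input = c(100, 30)) {
  t1 <- input[1] - 2                        # conv k3 valid
  tp <- floor((t1 - 3) / 3) + 1             # pool 3/3 valid
  t2 <- tp - 2                              # conv k3 valid
  data.frame(
    layer = c("input", "conv1d_1", "maxpool1d_1", "conv1d_2", "gru_1",
              "dense_1", "dense_2", "dense_3"),
    shape = c(paste(input, collapse = "x"),
              sprintf("%dx64", t1), sprintf("%dx64", tp),
              sprintf("%dx128", t2), "128", "64", "32", "9"),
    stringsAsFactors = FALSE
  )
}

# Glorot-uniform initializer
glorot <- function(fan_in, fan_out, n = fan_in * fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n, -lim, lim), fan_in, fan_out)
}

orthogonal_init <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

sfe_net_init <- function(channels = 30, classes = 9, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  list(
    W1 = glorot(3 * channels, 64), b1 = numeric(64),
    W2 = glorot(3 * 64, 128), b2 = numeric(128),
    Wx = glorot(128, 384), bx = numeric(384),
    Uz = orthogonal_init(128), Ur = orthogonal_init(128), Uh = orthogonal_init(128),
    Wd1 = glorot(128, 64), bd1 = numeric(64),
    Wd2 = glorot(64, 32), bd2 = numeric(32),
    Wd3 = glorot(32, classes), bd3 = numeric(classes)
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Stack a list of channels x samples windows into the time-major batch
# array (time, batch, channels); optional global scale division.
stack_windows <- function(windows, scale = 1) {
  tlen <- ncol(windows[[1]])
  ch <- nrow(windows[[1]])
  B <- length(windows)
  out <- array(0, dim = c(tlen, B, ch))
  for (b in seq_len(B)) out[, b, ] <- t(unclass(windows[[b]])) / scale
  out
}

# All batch tensors are kept as flat matrices with row index (t, b) =
# t + (b - 1) * T (time fastest); convolutions become gathers (cached
# linear-index matrices) followed by one BLAS matmul.
.net_idx_cache <- new.env(parent = emptyenv())

im2col_index <- function(tlen, B, C) {
  t_out <- tlen - 2
  rows_k <- lapply(1:3, function(k) {
    as.vector(outer(seq_len(t_out) + k - 1, (seq_len(B) - 1) * tlen, "+"))
  })
  IDX <- matrix(0L, t_out * B, 3 * C)
  for (k in 1:3) {
    IDX[, ((k - 1) * C + 1):(k * C)] <-
      outer(rows_k[[k]], (seq_len(C) - 1) * (tlen * B), "+")
  }
  list(IDX = IDX, rows = rows_k, t_out = t_out)
}

net_indices <- function(B) {
  key <- as.character(B)
  hit <- .net_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  ix <- list(
    c1 = im2col_index(100, B, 30),
    pool = lapply(1:3, function(k) {
      as.vector(outer(3 * seq_len(32) - 3 + k, (seq_len(B) - 1) * 98, "+"))
    }),
    c2 = im2col_index(32, B, 64),
    gru = lapply(1:30, function(t) seq.int(t, by = 30, length.out = B))
  )
  .net_idx_cache[[key]] <- ix
  ix
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# gather + trailing ones column (bias folded into the matmul)
gather_ones <- function(src, IDX) {
  n <- nrow(IDX)
  out <- matrix(1, n, ncol(IDX) + 1L)
  out[seq_len(n * ncol(IDX))] <- src[IDX]
  out
}

# Forward pass over a batch. X: (100, B, 30). Returns cache when training.
sfe_net_forward <- function(par, X, training = FALSE, dropout = 0.1,
                            rec_dropout = 0.1, keep_cache = training) {
  B <- dim(X)[2]
  ix <- net_indices(B)
  Xm <- X
  dim(Xm) <- c(100 * B, 30)
  M1 <- gather_ones(Xm, ix$c1$IDX)                  # (98B) x 91
  Z1 <- M1 %*% rbind(par$W1, par$b1)
  H1 <- Z1 * (Z1 > 0)                               # (98B) x 64
  s1 <- H1[ix$pool[[1]], , drop = FALSE]
  s2 <- H1[ix$pool[[2]], , drop = FALSE]
  s3 <- H1[ix$pool[[3]], , drop = FALSE]
  P <- pmax(s1, s2, s3)                             # (32B) x 64
  M2 <- gather_ones(P, ix$c2$IDX)                   # (30B) x 193
  Z2 <- M2 %*% rbind(par$W2, par$b2)
  H2 <- Z2 * (Z2 > 0)                               # (30B) x 128

  # GRU over 30 steps; row (t, b) = t + (b-1)*30
  if (training && dropout > 0) {
    Mi_b <- matrix(stats::rbinom(B * 128, 1, 1 - dropout), B, 128) / (1 - dropout)
    Mi <- Mi_b[rep(seq_len(B), each = 30), , drop = FALSE]
  } else {
    Mi_b <- NULL
    Mi <- NULL
  }
  H2d <- if (is.null(Mi)) H2 else H2 * Mi
  H2a <- cbind(H2d, 1)
  Xg <- H2a %*% rbind(par$Wx, par$bx)               # (30B) x 384
  Mr <- if (training && rec_dropout > 0) {
    matrix(stats::rbinom(B * 128, 1, 1 - rec_dropout), B, 128) / (1 - rec_dropout)
  } else NULL
  Uzr <- cbind(par$Uz, par$Ur)
  h <- matrix(0, B, 128)
  steps <- if (keep_cache) vector("list", 30) else NULL
  for (t in 1:30) {
    Xg_t <- Xg[ix$gru[[t]], , drop = FALSE]
    hd <- if (is.null(Mr)) h else h * Mr
    zr <- sigmoid(Xg_t[, 1:256, drop = FALSE] + hd %*% Uzr)
    z <- zr[, 1:128, drop = FALSE]
    r <- zr[, 129:256, drop = FALSE]
    rh <- r * hd
    hh <- tanh(Xg_t[, 257:384, drop = FALSE] + rh %*% par$Uh)
    h_new <- z * h + (1 - z) * hh
    if (keep_cache) steps[[t]] <- list(h_prev = h, hd = hd, z = z, r = r,
                                       hh = hh, rh = rh)
    h <- h_new
  }

  D1 <- pmax(sweep(h %*% par$Wd1, 2, par$bd1, "+"), 0)
  D2 <- pmax(sweep(D1 %*% par$Wd2, 2, par$bd2, "+"), 0)
  logits <- sweep(D2 %*% par$Wd3, 2, par$bd3, "+")
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)

  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(ix = ix, M1 = M1, Z1 = Z1, P = P,
                      s1 = s1, s2 = s2, s3 = s3,
                      M2 = M2, Z2 = Z2, H2a = H2a, Mi = Mi, Mr = Mr,
                      steps = steps, h = h, D1 = D1, D2 = D2, B = B)
  }
  out
}

# Backward pass; Y one-hot (B x 9). Returns gradient list matching par.
sfe_net_backward <- function(par, fw, Y) {
  cc <- fw$cache
  B <- cc$B
  g <- list()
  dlogits <- (fw$probs - Y) / B
  g$Wd3 <- crossprod(cc$D2, dlogits); g$bd3 <- colSums(dlogits)
  dD2 <- tcrossprod(dlogits, par$Wd3) * (cc$D2 > 0)
  g$Wd2 <- crossprod(cc$D1, dD2); g$bd2 <- colSums(dD2)
  dD1 <- tcrossprod(dD2, par$Wd2) * (cc$D1 > 0)
  g$Wd1 <- crossprod(cc$h, dD1); g$bd1 <- colSums(dD1)
  dh <- tcrossprod(dD1, par$Wd1)

  ix <- cc$ix
  dXg <- matrix(0, 30 * B, 384)
  g$Uz <- matrix(0, 128, 128); g$Ur <- matrix(0, 128, 128); g$Uh <- matrix(0, 128, 128)
  Mr <- cc$Mr
  for (t in 30:1) {
    st <- cc$steps[[t]]
    dz <- dh * (st$h_prev - st$hh)
    dhh <- dh * (1 - st$z)
    dh_prev <- dh * st$z
    da_hh <- dhh * (1 - st$hh^2)
    drh <- tcrossprod(da_hh, par$Uh)
    g$Uh <- g$Uh + crossprod(st$rh, da_hh)
    dr <- drh * st$hd
    dhd <- drh * st$r
    da_z <- dz * st$z * (1 - st$z)
    da_r <- dr * st$r * (1 - st$r)
    g$Uz <- g$Uz + crossprod(st$hd, da_z)
    g$Ur <- g$Ur + crossprod(st$hd, da_r)
    dhd <- dhd + tcrossprod(da_z, par$Uz) + tcrossprod(da_r, par$Ur)
    dh_prev <- dh_prev + if (is.null(Mr)) dhd else dhd * Mr
    rows <- ix$gru[[t]]
    dXg[rows, 1:128] <- da_z
    dXg[rows, 129:256] <- da_r
    dXg[rows, 257:384] <- da_hh
    dh <- dh_prev
  }
  gWx <- crossprod(cc$H2a, dXg)
  g$Wx <- gWx[1:128, , drop = FALSE]; g$bx <- gWx[129, ]
  dH2 <- tcrossprod(dXg, par$Wx)
  if (!is.null(cc$Mi)) dH2 <- dH2 * cc$Mi
  dH2 <- dH2 * (cc$Z2 > 0)
  gW2 <- crossprod(cc$M2, dH2)
  g$W2 <- gW2[1:192, , drop = FALSE]; g$b2 <- gW2[193, ]
  dM2 <- tcrossprod(dH2, par$W2)                    # (30B) x 192

  dP <- matrix(0, 32 * B, 64)
  for (k in 1:3) {
    rows <- ix$c2$rows[[k]]
    dP[rows, ] <- dP[rows, , drop = FALSE] + dM2[, ((k - 1) * 64 + 1):(k * 64)]
  }
  w2 <- (cc$s2 == cc$P)
  w1 <- (cc$s1 == cc$P) & !w2
  w3 <- !(w1 | w2)
  w1[w2] <- FALSE                                   # route ties to one slot
  dH1 <- matrix(0, 98 * B, 64)
  dH1[ix$pool[[1]], ] <- dP * w1
  dH1[ix$pool[[2]], ] <- dP * w2
  dH1[ix$pool[[3]], ] <- dP * w3
  dH1 <- dH1 * (cc$Z1 > 0)
  gW1 <- crossprod(cc$M1, dH1)
  g$W1 <- gW1[1:90, , drop = FALSE]; g$b1 <- gW1[91, ]
  g
}

#' Train the nine-class window classifier
#'
#' Mini-batch RMSprop on categorical cross-entropy; inputs are divided by a
#' single global scale (the pooled standard deviation of the training
#' windows) before entering the network. The weights with the best
#' validation accuracy across epochs are kept.
#'
#' @param windows List of 30 x 100 windows in the 5-50 Hz decoding band.
#' @param labels Character vector of [sfe_labels()] values, one per window.
#' @param epochs Training epochs (default 30).
#' @param batch_size Mini-batch size (default 128).
#' @param lr RMSprop learning rate (default 0.001).
#' @param dropout,rec_dropout GRU input / recurrent dropout rates (0.1).
#' @param val_fraction Fraction held out internally for checkpoint selection
#'   (default 0.15; stratified).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return An `sfe_net` model (parameters, label order, input scale,
#'   training history).
#' @export
train_sfe_net <- function(windows, labels, epochs = 30, batch_size = 128,
                          lr = 0.001, dropout = 0.1, rec_dropout = 0.1,
                          val_fraction = 0.15, seed = 1L, verbose = FALSE) {
  classes <- sfe_labels()
  labels <- as.character(labels)
  missing_cls <- setdiff(classes, labels)
  if (length(missing_cls)) {
    stop(sprintf("invalid dataset: class(es) absent from training set: %s",
                 paste(missing_cls, collapse = ", ")), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 7L))

  scale <- stats::sd(unlist(lapply(windows[seq(1, length(windows),
                                               length.out = min(200, length(windows)))],
                                   as.numeric)))
  X_all <- stack_windows(windows, scale)
  y_idx <- match(labels, classes)
  n <- length(windows)
  # stratified validation split for checkpoint selection
  val <- unlist(lapply(split(seq_len(n), y_idx), function(ix) {
    sample(ix, max(1, round(length(ix) * val_fraction)))
  }))
  tr <- setdiff(seq_len(n), val)
  Y_all <- matrix(0, n, length(classes))
  Y_all[cbind(seq_len(n), y_idx)] <- 1

  par <- sfe_net_init(channels = dim(X_all)[3], classes = length(classes),
                      seed = derive_seed(seed, 8L))
  cache_ms <- lapply(par, function(p) p * 0)
  rho <- 0.9; eps <- 1e-7
  best <- list(acc = -1, par = par)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_acc = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1, length(ord))]
      if (length(ix) < 2) next
      fw <- sfe_net_forward(par, X_all[, ix, , drop = FALSE], training = TRUE,
                            dropout = dropout, rec_dropout = rec_dropout)
      Y <- Y_all[ix, , drop = FALSE]
      losses <- c(losses, -mean(log(pmax(rowSums(fw$probs * Y), 1e-12))))
      g <- sfe_net_backward(par, fw, Y)
      for (nm in names(g)) {
        cache_ms[[nm]] <- rho * cache_ms[[nm]] + (1 - rho) * g[[nm]]^2
        par[[nm]] <- par[[nm]] - lr * g[[nm]] / (sqrt(cache_ms[[nm]]) + eps)
      }
    }
    vp <- sfe_net_forward(par, X_all[, val, , drop = FALSE])$probs
    vacc <- mean(max.col(vp, ties.method = "first") == y_idx[val])
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         val_acc = vacc))
    if (vacc > best$acc) best <- list(acc = vacc, par = par)
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  val_acc %.4f", ep,
                      mean(losses), vacc))
    }
  }
  structure(list(par = best$par, classes = classes, scale = scale,
                 val_acc = best$acc, history = history),
            class = "sfe_net")
}

#' @export
print.sfe_net <- function(x, ...) {
  cat(sprintf("<sfe_net> 9-class Conv1D-GRU window classifier (val acc %.3f)\n",
              x$val_acc))
  invisible(x)
}

#' Decode windows with a trained network (Step C)
#'
#' @param model An `sfe_net`.
#' @param window One 30 x 100 window in the decoding band.
#' @return List with `label` (argmax, ties to the lowest one-hot index) and
#'   `probs` (named nine-way distribution).
#' @export
step_c_decode <- function(model, window) {
  p <- sfe_net_predict(model, list(window))
  list(label = model$classes[max.col(p, ties.method = "first")],
       probs = stats::setNames(p[1, ], model$classes))
}

#' @rdname step_c_decode
#' @param windows List of windows.
#' @param batch_size Prediction batch size.
#' @return `sfe_net_predict` returns an n x 9 probability matrix.
#' @export
sfe_net_predict <- function(model, windows, batch_size = 256) {
  n <- length(windows)
  out <- matrix(0, n, length(model$classes))
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    X <- stack_windows(windows[ix], model$scale)
    out[ix, ] <- sfe_net_forward(model$par, X)$probs
  }
  colnames(out) <- model$classes
  out
}

#' @rdname step_c_decode
#' @return `sfe_net_classify` returns the character label vector.
#' @export
sfe_net_classify <- function(model, windows, batch_size = 256) {
  p <- sfe_net_predict(model, windows, batch_size)
  model$classes[max.col(p, ties.method = "first")]
}
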