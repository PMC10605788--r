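# 25-layer 1D convolutional network for surface classification.
#
# Five blocks of [conv(k=3, s=1, same) -> ReLU -> batch norm ->
# max-pool(3, s=3, ceil)] with 64/64/128/128/128 filters, dropout 0.5
# after the pools of blocks 3-5, then flatten and a 9-unit softmax
# dense layer. Implemented directly on BLAS matrix products: a batch
# lives as a (B*T) x C matrix with time fastest within a sample, and a
# length-3 convolution is the sum of three row-shifted matrix products.

CONV_FILTERS <- c(64L, 64L, 128L, 128L, 128L)
BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

# temporal lengths after each of the five ceil-mode pools
.pool_lengths <- function(L) {
  out <- integer(5)
  cur <- L
  for (i in 1:5) {
    cur <- ceiling(cur / 3)
    out[i] <- cur
  }
  out
}

#' Build the surface-classification CNN
#'
#' Constructs the 25-layer architecture for an `L x C` input window:
#' five convolution blocks (filters 64, 64, 128, 128, 128; kernel 3,
#' stride 1, length-preserving padding; ReLU; batch normalization;
#' max-pooling size 3 stride 3 in ceil mode so every window length from
#' 100 to 500 samples survives all five pools), dropout rate 0.5 after
#' the pools of blocks 3-5, a flatten layer and a dense softmax output.
#' Weights are Glorot-uniform initialized from the current RNG stream
#' (or `seed` when given).
#'
#' @param input_length Window length `L` in samples.
#' @param n_channels Number of fused input channels `C`.
#' @param n_classes Number of output classes.
#' @param seed Optional integer seed for weight initialization.
#' @param bn_momentum Momentum of the batch-norm running statistics.
#'   The default 0.99 suits long runs (hundreds of optimizer steps);
#'   small-scale runs need a smaller value so the inference statistics
#'   converge within the available steps.
#' @return Object of class `surface_cnn`.
#' @export
build_surface_cnn <- function(input_length, n_channels, n_classes = 9,
                              seed = NULL, bn_momentum = BN_MOMENTUM) {
  L <- as.integer(input_length); C <- as.integer(n_channels)
  if (L < 9) stop("build_surface_cnn: input too short for five pooling stages")
  if (C < 1) stop("build_surface_cnn: need at least one channel")
  if (!is.null(seed)) set.seed(seed)
  lens <- .pool_lengths(L)
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list()
  cin <- C
  for (b in 1:5) {
    cout <- CONV_FILTERS[b]
    fan_in <- 3 * cin; fan_out <- 3 * cout
    params[[paste0("conv", b)]] <- list(
      W = glorot(3 * cin, cout, fan_in, fan_out),  # 3 kernel taps stacked
      b = numeric(cout))
    params[[paste0("bn", b)]] <- list(
      gamma = rep(1, cout), beta = numeric(cout),
      rmean = numeric(cout), rvar = rep(1, cout))
    cin <- cout
  }
  n_feat <- lens[5] * CONV_FILTERS[5]
  params$dense <- list(W = glorot(n_feat, n_classes, n_feat, n_classes),
                       b = numeric(n_classes))
  structure(list(input_length = L, n_channels = C, n_classes = n_classes,
                 pool_lengths = lens, n_features = n_feat,
                 bn_momentum = bn_momentum,
                 params = params, trained = FALSE),
            class = "surface_cnn")
}

#' Ordered layer manifest of the network
#'
#' @param model A `surface_cnn`.
#' @return data.frame with 25 rows: `layer`, `block`, `kind`,
#'   `output_length`, `output_channels`, `spec`.
#' @export
layer_manifest <- function(model) {
  stopifnot(inherits(model, "surface_cnn"))
  rows <- list()
  len <- model$input_length
  add <- function(block, kind, out_len, out_ch, spec) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = length(rows) + 1L, block = block, kind = kind,
      output_length = out_len, output_channels = out_ch, spec = spec,
      stringsAsFactors = FALSE)
  }
  for (b in 1:5) {
    ch <- CONV_FILTERS[b]
    add(b, "conv1d", len, ch,
        sprintf("filters=%d, kernel_size=3, strides=1, padding=same", ch))
    add(b, "relu", len, ch, "-")
    add(b, "batch_norm", len, ch, sprintf("epsilon=%g", BN_EPS))
    len <- ceiling(len / 3)
    add(b, "max_pool1d", len, ch, "pool_size=3, strides=3, ceil mode")
    if (b >= 3) add(b, "dropout", len, ch, "rate=0.5")
  }
  add(6, "flatten", 1L, model$n_features, "-")
  add(6, "dense", 1L, model$n_classes,
      sprintf("units=%d, activation=softmax", model$n_classes))
  do.call(rbind, rows)
}

#' Count model parameters
#'
#' @param model A `surface_cnn`.
#' @param breakdown Return the per-kind split instead of the total.
#' @return Integer total parameter count (trainable weights plus the
#'   two non-trainable running statistics per batch-norm channel), or,
#'   with `breakdown = TRUE`, a list with `trainable`, `non_trainable`
#'   and `total`.
#' @export
count_parameters <- function(model, breakdown = FALSE) {
  stopifnot(inherits(model, "surface_cnn"))
  trainable <- 0L; non_trainable <- 0L
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    if (startsWith(nm, "bn")) {
      trainable <- trainable + length(p$gamma) + length(p$beta)
      non_trainable <- non_trainable + length(p$rmean) + length(p$rvar)
    } else {
      trainable <- trainable + length(p$W) + length(p$b)
    }
  }
  if (breakdown)
    list(trainable = trainable, non_trainable = non_trainable,
         total = trainable + non_trainable)
  else as.integer(trainable + non_trainable)
}

#' @export
print.surface_cnn <- function(x, ...) {
  cat("<surface_cnn> input ", x$input_length, " x ", x$n_channels,
      " -> ", x$n_classes, " classes; ", count_parameters(x),
      " parameters (", if (x$trained) "trained" else "untrained", ")\n",
      sep = "")
  invisible(x)
}

# ---- batched tensor helpers -----------------------------------------

# (L, C, B) array slice -> (B*L) x C matrix, time fastest within sample
.batch_matrix <- function(x, idx) {
  a <- x[, , idx, drop = FALSE]
  d <- dim(a)
  m <- matrix(aperm(a, c(1, 3, 2)), d[1] * d[3], d[2])
  attr(m, "B") <- d[3]; attr(m, "L") <- d[1]
  m
}

# row-shift within each sample: row (b, t) of result = X[(b, t + d)],
# zero where t + d leaves [1, L]
.shift_rows <- function(X, B, L, d) {
  tvec <- rep.int(seq_len(L), B)
  ok <- tvec + d >= 1L & tvec + d <= L
  Y <- matrix(0, nrow(X), ncol(X))
  Y[ok, ] <- X[which(ok) + d, ]
  Y
}

.conv_fwd <- function(X, p, B, L) {
  # im2col for kernel 3: the three row-shifted copies side by side,
  # so the convolution is one matrix product
  Xcat <- cbind(.shift_rows(X, B, L, -1L), X, .shift_rows(X, B, L, 1L))
  Y <- Xcat %*% p$W
  Y <- Y + rep(p$b, each = nrow(Y))
  list(Y = Y, Xcat = Xcat)
}

.conv_bwd <- function(dY, cache, p, B, L) {
  dW <- crossprod(cache$Xcat, dY)
  db <- colSums(dY)
  dXcat <- tcrossprod(dY, p$W)
  C <- ncol(dXcat) / 3L
  dX <- .shift_rows(dXcat[, 1:C, drop = FALSE], B, L, 1L) +
    dXcat[, C + 1:C, drop = FALSE] +
    .shift_rows(dXcat[, 2L * C + 1:C, drop = FALSE], B, L, -1L)
  list(dX = dX, grad = list(W = dW, b = db))
}

.bn_fwd <- function(X, p, training) {
  if (training) {
    n <- nrow(X)
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * rep(invstd, each = n)
    Y <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
    list(Y = Y, xhat = xhat, invstd = invstd, mu = mu, var = v)
  } else {
    n <- nrow(X)
    invstd <- 1 / sqrt(p$rvar + BN_EPS)
    Y <- (X - rep(p$rmean, each = n)) * rep(p$gamma * invstd, each = n) +
      rep(p$beta, each = n)
    list(Y = Y)
  }
}

.bn_bwd <- function(dY, cache, p) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(p$gamma, each = n)
  dX <- (dxhat - rep(colMeans(dxhat), each = n) -
           cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
    rep(cache$invstd, each = n)
  list(dX = dX, grad = list(gamma = dgamma, beta = dbeta))
}

.pool_fwd <- function(X, B, L) {
  Lo <- ceiling(L / 3)
  C <- ncol(X)
  # output row (b, u) pools input rows (b, 3u-2 .. min(3u, L))
  u <- rep.int(seq_len(Lo), B)
  base <- rep((seq_len(B) - 1L) * L, each = Lo)
  i1 <- base + 3L * u - 2L
  Y <- X[i1, , drop = FALSE]
  src <- matrix(i1, length(i1), C)
  for (d in 1:2) {
    ok <- 3L * u - 2L + d <= L
    idx <- i1[ok] + d
    cand <- X[idx, , drop = FALSE]
    cur <- Y[ok, , drop = FALSE]
    better <- cand > cur
    cur[better] <- cand[better]
    Y[ok, ] <- cur
    s <- src[ok, , drop = FALSE]
    s[better] <- matrix(idx, length(idx), C)[better]
    src[ok, ] <- s
  }
  list(Y = Y, src = src, n_in = nrow(X), Lo = Lo)
}

.pool_bwd <- function(dY, cache) {
  C <- ncol(dY)
  dX <- numeric(cache$n_in * C)
  lin <- as.vector(cache$src) +
    rep((seq_len(C) - 1L) * cache$n_in, each = nrow(dY))
  dX[lin] <- as.vector(dY)
  matrix(dX, cache$n_in, C)
}

.flatten_fwd <- function(X, B, L) {
  C <- ncol(X)
  t(matrix(aperm(array(X, c(L, B, C)), c(1, 3, 2)), L * C, B))
}

.flatten_bwd <- function(dF, B, L, C) {
  matrix(aperm(array(t(dF), c(L, C, B)), c(1, 3, 2)), L * B, C)
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# full forward pass; returns class probabilities and (when training)
# the per-layer caches needed for the backward pass
.cnn_forward <- function(model, xb, training = FALSE, dropout_rate = 0.5) {
  B <- attr(xb, "B"); L <- attr(xb, "L")
  p <- model$params
  caches <- list()
  X <- xb
  for (blk in 1:5) {
    cv <- .conv_fwd(X, p[[paste0("conv", blk)]], B, L)
    A <- cv$Y
    relu_mask <- A > 0
    A <- A * relu_mask
    bn <- .bn_fwd(A, p[[paste0("bn", blk)]], training)
    pl <- .pool_fwd(bn$Y, B, L)
    Xn <- pl$Y
    drop_mask <- NULL
    if (blk >= 3 && training && dropout_rate > 0) {
      drop_mask <- matrix(
        (stats::runif(length(Xn)) >= dropout_rate) / (1 - dropout_rate),
        nrow(Xn), ncol(Xn))
      Xn <- Xn * drop_mask
    }
    caches[[blk]] <- list(conv = cv, relu_mask = relu_mask, bn = bn,
                          pool = pl, drop_mask = drop_mask, L = L)
    X <- Xn
    L <- pl$Lo
  }
  Fm <- .flatten_fwd(X, B, L)
  logits <- Fm %*% p$dense$W + rep(p$dense$b, each = B)
  probs <- .softmax(logits)
  list(probs = probs, Fm = Fm, caches = caches, B = B, L_last = L)
}

# backward pass from labels (0-based ordinals); returns gradients in
# the same nested structure as model$params and the batch loss
.cnn_backward <- function(model, fwd, y) {
  p <- model$params
  B <- fwd$B
  probs <- fwd$probs
  onehot <- matrix(0, B, model$n_classes)
  onehot[cbind(seq_len(B), y + 1L)] <- 1
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), y + 1L)], 1e-12)))
  dlogits <- (probs - onehot) / B
  grads <- list()
  grads$dense <- list(W = crossprod(fwd$Fm, dlogits), b = colSums(dlogits))
  dF <- dlogits %*% t(p$dense$W)
  dX <- .flatten_bwd(dF, B, fwd$L_last, CONV_FILTERS[5])
  for (blk in 5:1) {
    cc <- fwd$caches[[blk]]
    if (!is.null(cc$drop_mask)) dX <- dX * cc$drop_mask
    dX <- .pool_bwd(dX, cc$pool)
    bn <- .bn_bwd(dX, cc$bn, p[[paste0("bn", blk)]])
    grads[[paste0("bn", blk)]] <- bn$grad
    dX <- bn$dX * cc$relu_mask
    cv <- .conv_bwd(dX, cc$conv, p[[paste0("conv", blk)]], B, cc$L)
    grads[[paste0("conv", blk)]] <- cv$grad
    dX <- cv$dX
  }
  list(loss = loss, grads = grads)
}

# update batch-norm running statistics after a training step
.bn_update_running <- function(model, fwd) {
  mom <- model$bn_momentum %||% BN_MOMENTUM
  for (blk in 1:5) {
    nm <- paste0("bn", blk)
    bn <- fwd$caches[[blk]]$bn
    model$params[[nm]]$rmean <- mom * model$params[[nm]]$rmean +
      (1 - mom) * bn$mu
    model$params[[nm]]$rvar <- mom * model$params[[nm]]$rvar +
      (1 - mom) * bn$var
  }
  model
}

#' Predict class probabilities for a segment set
#'
#' @param model A trained (or freshly built) `surface_cnn`.
#' @param set A `segment_set` (or a bare `L x C x n` array) whose shape
#'   matches the model input.
#' @param batch_size Mini-batch size used during inference.
#' @return Numeric matrix `n x n_classes` of softmax probabilities;
#'   columns follow [surface_levels()].
#' @export
predict_proba <- function(model, set, batch_size = 256) {
  x <- if (inherits(set, "segment_set")) set$x else set
  stopifnot(length(dim(x)) == 3L,
            dim(x)[1] == model$input_length,
            dim(x)[2] == model$n_channels)
  n <- dim(x)[3]
  out <- matrix(NA_real_, n, model$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- .batch_matrix(x, i:j)
    out[i:j, ] <- .cnn_forward(model, xb, training = FALSE)$probs
    i <- j + 1L
  }
  colnames(out) <- surface_levels()[seq_len(model$n_classes)]
  out
}

#' Predict class ordinals (0-based) for a segment set
#' @inheritParams predict_proba
#' @return Integer vector of predicted class ordinals.
#' @export
predict_class <- function(model, set, batch_size = 256) {
  max.col(predict_proba(model, set, batch_size)) - 1L
}

# ---- Adam optimizer over a nested parameter list --------------------

.adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (k in seq_along(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / b1t) / (sqrt(v / b2t) + eps)
      list(p = p, m = m, v = v)
    }
  }
  # running stats are not optimizer-updated
  skip <- function(nm) startsWith(nm, "bn")
  for (nm in names(params)) {
    if (skip(nm)) {
      sub <- c("gamma", "beta")
      for (s in sub) {
        r <- upd(params[[nm]][[s]], grads[[nm]][[s]],
                 state$m[[nm]][[s]], state$v[[nm]][[s]])
        params[[nm]][[s]] <- r$p
        state$m[[nm]][[s]] <- r$m; state$v[[nm]][[s]] <- r$v
      }
    } else {
      r <- upd(params[[nm]], grads[[nm]],
               state$m[[nm]], state$v[[nm]])
      params[[nm]] <- r$p
      state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}
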