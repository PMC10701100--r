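# Minimal dense feed-forward network (ReLU hidden layers, sigmoid output)
# trained with binary cross-entropy and Adam, with early stopping on a
# held-out split.  Sized for the small fixed head used by the sequence
# fallback model (128 -> 64 -> 1); plain matrix ops are ample at that scale.

mlp_init <- function(dims, seed) {
  withr::with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1L)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                    sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  nl <- length(par$W)
  A <- list(X)
  for (l in seq_len(nl)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], `+`)
    A[[l + 1L]] <- if (l < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  A
}

mlp_bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# Full-batch Adam with early stopping; returns best-validation parameters.
mlp_train <- function(X, y, hidden = c(128L, 64L), seed = 1L,
                      epochs = 300L, lr = 1e-3, val_frac = 0.2,
                      patience = 25L) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L)
    abort("degenerate single-class training labels")
  dims <- c(ncol(X), hidden, 1L)
  par <- mlp_init(dims, seed)
  nl <- length(par$W)

  idx <- withr::with_seed(seed + 1L, sample(nrow(X)))
  nval <- max(1L, round(val_frac * nrow(X)))
  val <- idx[seq_len(nval)]; trn <- idx[-seq_len(nval)]
  Xt <- X[trn, , drop = FALSE]; yt <- y[trn]
  Xv <- X[val, , drop = FALSE]; yv <- y[val]

  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, par = par); wait <- 0L

  for (t in seq_len(epochs)) {
    A <- mlp_forward(par, Xt)
    p <- as.numeric(A[[nl + 1L]])
    delta <- matrix((p - yt) / length(yt), ncol = 1L)  # dL/dZ_out for BCE+sigmoid
    for (l in rev(seq_len(nl))) {
      gW <- t(A[[l]]) %*% delta
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      par$W[[l]] <- par$W[[l]] - lr * (mW[[l]] / (1 - b1^t)) /
        (sqrt(vW[[l]] / (1 - b2^t)) + eps)
      par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / (1 - b1^t)) /
        (sqrt(vb[[l]] / (1 - b2^t)) + eps)
    }
    vp <- as.numeric(mlp_forward(par, Xv)[[nl + 1L]])
    vloss <- mlp_bce(vp, yv)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, par = par); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  c(best, list(dims = dims))
}

mlp_predict <- function(fit, X) {
  as.numeric(mlp_forward(fit$par, X)[[length(fit$dims)]])
}
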