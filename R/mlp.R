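# A small multi-layer perceptron classifier: 2-3 hidden ReLU layers of
# uniform width, sigmoid output, binary cross-entropy loss, Adam updates in
# seeded mini-batches for a fixed number of epochs. Written here because the
# model zoo needs multi-hidden-layer networks with probability output.

.cs_mlp_init <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    # He initialization for ReLU layers
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0,
                                  sqrt(2 / sizes[i])),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- rep(0, sizes[i + 1L])
  }
  list(W = W, b = b)
}

.cs_mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (i in seq_len(L)) {
    z <- sweep(acts[[i]] %*% par$W[[i]], 2, par$b[[i]], "+")
    acts[[i + 1L]] <- if (i < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

mlp_fit <- function(X, y01, layers = 2L, width = 100L, batch = 100L,
                    seed = 1L, epochs = 40L, lr = 1e-3) {
  stopifnot(layers %in% c(2L, 3L), all(y01 %in% c(0, 1)))
  X <- as.matrix(X)
  sizes <- c(ncol(X), rep(width, layers), 1L)
  par <- .cs_mlp_init(sizes, seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  n <- nrow(X)
  set.seed(seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      acts <- .cs_mlp_forward(par, X[idx, , drop = FALSE])
      m <- length(idx)
      delta <- (acts[[L + 1L]] - y01[idx]) / m  # dL/dz for sigmoid + BCE
      t <- t + 1L
      for (i in L:1) {
        gW <- crossprod(acts[[i]], delta)
        gb <- colSums(delta)
        if (i > 1) {
          delta <- (delta %*% t(par$W[[i]])) * (acts[[i]] > 0)
        }
        mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW
        vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW^2
        mb[[i]] <- b1 * mb[[i]] + (1 - b1) * gb
        vb[[i]] <- b2 * vb[[i]] + (1 - b2) * gb^2
        corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
        par$W[[i]] <- par$W[[i]] - lr * (mW[[i]] / corr1) /
          (sqrt(vW[[i]] / corr2) + eps)
        par$b[[i]] <- par$b[[i]] - lr * (mb[[i]] / corr1) /
          (sqrt(vb[[i]] / corr2) + eps)
      }
    }
  }
  structure(list(par = par, p = ncol(X)), class = "cs_mlp")
}

mlp_predict <- function(fit, X) {
  stopifnot(inherits(fit, "cs_mlp"), ncol(X) == fit$p)
  acts <- .cs_mlp_forward(fit$par, as.matrix(X))
  as.numeric(acts[[length(acts)]])
}
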