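# Minimal feed-forward network engine: 3x3 same-padding convolutions via
# im2col + BLAS, ReLU, 2x2 max pooling, dense layers and a softmax
# cross-entropy head, with analytic backpropagation and an Adam optimiser.
# Batches are arrays of shape (H, W, C, N). Layers carry a `trainable`
# flag; frozen layers receive no parameter updates, which is what makes a
# frozen backbone byte-identical before and after training.

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(c_in, c_out, trainable = TRUE) {
  list(type = "conv", c_in = c_in, c_out = c_out,
       W = he_init(9 * c_in, c_out, 9 * c_in),
       b = numeric(c_out), trainable = trainable)
}
layer_relu <- function() list(type = "relu", trainable = FALSE)
layer_pool <- function() list(type = "pool", trainable = FALSE)
layer_flatten <- function() list(type = "flatten", trainable = FALSE)
layer_dense <- function(n_in, n_out, trainable = TRUE) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       W = he_init(n_in, n_out, n_in), b = numeric(n_out),
       trainable = trainable)
}

# im2col for 3x3 kernels, stride 1, zero padding 1. X: (H, W, C, N).
# Returns a (H*W*N) x (9*C) matrix; row order (h, w, n) column-major.
im2col3 <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Xp <- array(0, c(H + 2, W + 2, C, N))
  Xp[2:(H + 1), 2:(W + 1), , ] <- X
  cols <- matrix(0, H * W * N, 9 * C)
  o <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      sl <- Xp[dy + (1:H), dx + (1:W), , , drop = FALSE]
      sl <- aperm(sl, c(1, 2, 4, 3))      # (H, W, N, C)
      dim(sl) <- c(H * W * N, C)
      cols[, o * C + (1:C)] <- sl
      o <- o + 1L
    }
  }
  cols
}

# Scatter-add of column gradients back to the input array.
col2im3 <- function(dcols, H, W, C, N) {
  dXp <- array(0, c(H + 2, W + 2, C, N))
  o <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      sl <- dcols[, o * C + (1:C)]
      dim(sl) <- c(H, W, N, C)
      sl <- aperm(sl, c(1, 2, 4, 3))
      dXp[dy + (1:H), dx + (1:W), , ] <- dXp[dy + (1:H), dx + (1:W), , ] + sl
      o <- o + 1L
    }
  }
  dXp[2:(H + 1), 2:(W + 1), , , drop = FALSE]
}

layer_forward <- function(layer, X) {
  switch(layer$type,
    conv = {
      d <- dim(X)
      cols <- im2col3(X)
      out <- sweep(cols %*% layer$W, 2, layer$b, "+")
      dim(out) <- c(d[1], d[2], d[4], layer$c_out)
      list(out = aperm(out, c(1, 2, 4, 3)), cache = list(cols = cols, dim = d))
    },
    relu = {
      out <- pmax(X, 0)
      list(out = out, cache = X > 0)
    },
    pool = {
      d <- dim(X)
      i1 <- seq(1, d[1], 2); i2 <- seq(2, d[1], 2)
      j1 <- seq(1, d[2], 2); j2 <- seq(2, d[2], 2)
      s <- list(X[i1, j1, , , drop = FALSE], X[i2, j1, , , drop = FALSE],
                X[i1, j2, , , drop = FALSE], X[i2, j2, , , drop = FALSE])
      out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
      list(out = out, cache = list(slices = s, dim = d, out = out))
    },
    flatten = {
      d <- dim(X)
      dim(X) <- c(prod(d[1:3]), d[4])
      list(out = X, cache = d)
    },
    dense = {
      list(out = crossprod(layer$W, X) + layer$b, cache = X)
    })
}

layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
    conv = {
      d <- cache$dim
      dmat <- aperm(dOut, c(1, 2, 4, 3))
      dim(dmat) <- c(d[1] * d[2] * d[4], layer$c_out)
      dW <- crossprod(cache$cols, dmat)
      db <- colSums(dmat)
      dX <- col2im3(dmat %*% t(layer$W), d[1], d[2], d[3], d[4])
      list(dX = dX, dW = dW, db = db)
    },
    relu = list(dX = dOut * cache),
    pool = {
      d <- cache$dim
      dX <- array(0, d)
      i1 <- seq(1, d[1], 2); i2 <- seq(2, d[1], 2)
      j1 <- seq(1, d[2], 2); j2 <- seq(2, d[2], 2)
      idx <- list(list(i1, j1), list(i2, j1), list(i1, j2), list(i2, j2))
      assigned <- array(FALSE, dim(cache$out))
      for (k in 1:4) {
        m <- (cache$slices[[k]] == cache$out) & !assigned
        dX[idx[[k]][[1]], idx[[k]][[2]], , ] <- dOut * m
        assigned <- assigned | m
      }
      list(dX = dX)
    },
    flatten = {
      dim(dOut) <- cache
      list(dX = dOut)
    },
    dense = {
      list(dX = layer$W %*% dOut,
           dW = cache %*% t(dOut), db = rowSums(dOut))
    })
}

network_forward <- function(layers, X, keep_cache = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], X)
    X <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(logits = X, caches = caches)
}

softmax_probs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Y: one-hot matrix (K x N). Returns loss and dLogits.
softmax_ce <- function(logits, Y) {
  probs <- softmax_probs(logits)
  n <- ncol(Y)
  loss <- -sum(Y * log(pmax(probs, 1e-12))) / n
  list(loss = loss, probs = probs, dLogits = (probs - Y) / n)
}

network_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    g <- layer_backward(layers[[i]], caches[[i]], dOut)
    dOut <- g$dX
    grads[[i]] <- g
  }
  grads
}

# Scale all gradients so their global L2 norm does not exceed `max_norm`.
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  sq <- 0
  for (g in grads) {
    if (!is.null(g$dW)) sq <- sq + sum(g$dW^2) + sum(g$db^2)
  }
  nrm <- sqrt(sq)
  if (nrm <= max_norm) return(grads)
  f <- max_norm / nrm
  lapply(grads, function(g) {
    if (!is.null(g$dW)) { g$dW <- g$dW * f; g$db <- g$db * f }
    g
  })
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (is.null(l$W) || !isTRUE(l$trainable)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$db
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$db^2
    l$W <- l$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    l$b <- l$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    layers[[i]] <- l
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
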