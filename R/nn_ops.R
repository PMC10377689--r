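# Internal layer helpers used by the network. Activation tensors are arrays
# (H, W, C, B); dense activations are feature-major matrices (d x B).
# ReLU and its gradient mask live in the compiled kernels (relu_inplace,
# relu_grad_inplace).

# Batch normalization over (H, W, B) per channel. `state` carries running
# mean/var used in eval mode; momentum 0.9, eps 1e-5. Returns y, an updated
# state, and a cache for the backward pass.
bn_fwd <- function(x, gamma, beta, state, training) {
  eps <- 1e-5
  momentum <- 0.9
  d <- dim(x)
  C <- d[3]
  n <- d[1] * d[2] * d[4]
  y <- x
  cache <- list(mu = numeric(C), var = numeric(C), xhat = x)
  for (c in seq_len(C)) {
    xc <- x[, , c, , drop = FALSE]
    if (training) {
      mu <- mean(xc)
      v <- mean((xc - mu)^2)
      state$mean[c] <- momentum * state$mean[c] + (1 - momentum) * mu
      state$var[c] <- momentum * state$var[c] + (1 - momentum) * v
    } else {
      mu <- state$mean[c]
      v <- state$var[c]
    }
    xhat <- (xc - mu) / sqrt(v + eps)
    cache$mu[c] <- mu
    cache$var[c] <- v
    cache$xhat[, , c, ] <- xhat
    y[, , c, ] <- gamma[c] * xhat + beta[c]
  }
  list(y = y, state = state, cache = cache)
}

bn_bwd <- function(dy, x, gamma, cache) {
  eps <- 1e-5
  d <- dim(x)
  C <- d[3]
  n <- d[1] * d[2] * d[4]
  dx <- dy
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dyc <- dy[, , c, , drop = FALSE]
    xhat <- cache$xhat[, , c, , drop = FALSE]
    xm <- x[, , c, , drop = FALSE] - cache$mu[c]
    ivar <- 1 / sqrt(cache$var[c] + eps)
    dgamma[c] <- sum(dyc * xhat)
    dbeta[c] <- sum(dyc)
    dxhat <- dyc * gamma[c]
    dvar <- sum(dxhat * xm) * (-0.5) * ivar^3
    dmu <- -sum(dxhat) * ivar + dvar * mean(-2 * xm)
    dx[, , c, ] <- dxhat * ivar + dvar * 2 * xm / n + dmu / n
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Dense layer on feature-major input (in x B): y = t(W) x + b, W is (in x out).
dense_fwd <- function(x, W, b) {
  crossprod(W, x) + b
}

dense_bwd <- function(x, W, dy) {
  list(dx = W %*% dy, dW = x %*% t(dy), db = rowSums(dy))
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
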