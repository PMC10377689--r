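#' Network configuration
#'
#' Hyper-parameters of the dual-branch network. The default geometry is a
#' 28 x 28 x 1 input image, a 20-dimensional latent space in both branches,
#' three parallel multiscale kernels (3, 5, 7) with 10 filters each followed
#' by 3 x 3 convolutions with 20 filters, and a softmax classifier on the
#' additively fused latent vector `m + z`.
#'
#' Variants (ablations):
#' \describe{
#'   \item{`msaenet`}{full dual-branch model.}
#'   \item{`multiscale`}{autoencoder branch removed; `fused = m`; the
#'     reconstruction weight is forced to 0.}
#'   \item{`ae`}{multiscale branch removed; `fused = z`.}
#'   \item{`singlescale`}{all three stage-1 kernels set to 3 x 3.}
#'   \item{`withoutloss`}{center-loss weight forced to 0.}
#'   \item{`rawdata`}{the input is the raw `C x T` epoch as a single-channel
#'     image (feature pre-extraction bypassed); the interior architecture is
#'     unchanged apart from the input-dependent flatten sizes.}
#' }
#'
#' @param input_size side of the square input image; must be divisible by 4
#'   (two pooling halvings in the encoder).
#' @param latent_dim latent width of both branches.
#' @param multiscale_kernels odd kernel sizes of the three parallel stage-1
#'   convolutions.
#' @param stage1_filters,stage2_filters filters per multiscale stage.
#' @param n_classes number of classes M.
#' @param variant one of the names above.
#' @param center_alpha learning rate of the non-gradient center update,
#'   in `[0, 1]`.
#' @return an object of class `msaenet_config`.
#' @export
msaenet_config <- function(input_size = 28, latent_dim = 20,
                           multiscale_kernels = c(3, 5, 7),
                           stage1_filters = 10, stage2_filters = 20,
                           n_classes = 2,
                           variant = c("msaenet", "multiscale", "ae",
                                       "singlescale", "withoutloss",
                                       "rawdata"),
                           center_alpha = 0.5) {
  variant <- match.arg(variant)
  if (!is_count(latent_dim, 1L)) stop_invalid("latent_dim must be >= 1")
  if (!is_count(n_classes, 2L)) stop_invalid("n_classes must be >= 2")
  if (length(multiscale_kernels) != 3L ||
      any(multiscale_kernels %% 2 != 1) || any(multiscale_kernels < 1)) {
    stop_invalid("multiscale_kernels must be three odd sizes >= 1")
  }
  if (!is_number(center_alpha) || center_alpha < 0 || center_alpha > 1) {
    stop_invalid("center_alpha must be in [0, 1]")
  }
  structure(list(input_size = as.integer(input_size),
                 latent_dim = as.integer(latent_dim),
                 multiscale_kernels = as.integer(multiscale_kernels),
                 stage1_filters = as.integer(stage1_filters),
                 stage2_filters = as.integer(stage2_filters),
                 n_classes = as.integer(n_classes), variant = variant,
                 center_alpha = center_alpha),
            class = "msaenet_config")
}

#' Loss weights of the fused objective
#'
#' Weights of the three loss terms: reconstruction MSE (`beta1`),
#' cross-entropy (`beta2`) and center loss (`beta3`). The defaults
#' `(0.5, 1.0, 0.5)` put the largest weight on the classification term.
#'
#' @param beta1,beta2,beta3 non-negative finite weights.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(beta1 = 0.5, beta2 = 1.0, beta3 = 0.5) {
  for (b in c(beta1, beta2, beta3)) {
    if (!is_number(b) || b < 0) stop_invalid("loss weights must be finite and >= 0")
  }
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3),
            class = "loss_weights")
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build the dual-branch network
#'
#' Allocates and initializes all trainable parameters (variance-scaling
#' fan-in initialization), the batch-norm running statistics and the class
#' centers. All activations are ReLU except the softmax output.
#'
#' @param cfg an [msaenet_config()].
#' @param input_dim optional `c(H, W)` overriding the square
#'   `input_size x input_size` input (used by the `rawdata` variant, where the
#'   input is the raw `C x T` epoch). Both sides must be divisible by 4.
#' @param seed integer seed for the parameter initialization; `NULL` uses the
#'   current RNG state.
#' @return an object of class `msaenet_model`.
#' @export
build_model <- function(cfg, input_dim = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "msaenet_config"))
  hw <- input_dim %||% c(cfg$input_size, cfg$input_size)
  if (any(hw %% 4 != 0)) {
    stop_invalid("input dimensions (", paste(hw, collapse = " x "),
                 ") must be divisible by 4 (two pooling halvings)")
  }
  if (!is.null(seed)) set.seed(seed)
  H <- hw[1]; W <- hw[2]
  f1 <- cfg$stage1_filters; f2 <- cfg$stage2_filters
  L <- cfg$latent_dim; M <- cfg$n_classes
  use_ae <- cfg$variant != "multiscale"
  use_ms <- cfg$variant != "ae"
  kernels <- if (cfg$variant == "singlescale") c(3L, 3L, 3L) else
    cfg$multiscale_kernels
  flat_ae <- (H %/% 4) * (W %/% 4) * f1
  flat_ms <- H * W * 3L * f2
  p <- list()
  bn <- list()
  if (use_ae) {
    p$enc1_W <- he_init(c(3, 3, 1, 1), 9);            p$enc1_b <- numeric(1)
    p$bn1_gamma <- rep(1, 1);                         p$bn1_beta <- numeric(1)
    p$enc2_W <- he_init(c(3, 3, 1, f1), 9);           p$enc2_b <- numeric(f1)
    p$bn2_gamma <- rep(1, f1);                        p$bn2_beta <- numeric(f1)
    p$encz_W <- he_init(c(flat_ae, L), flat_ae);      p$encz_b <- numeric(L)
    p$dec1_W <- he_init(c(L, flat_ae), L);            p$dec1_b <- numeric(flat_ae)
    p$tc1_W <- he_init(c(3, 3, f1, f1), 9 * f1);      p$tc1_b <- numeric(f1)
    p$tc2_W <- he_init(c(3, 3, 1, f1), 9 * f1);       p$tc2_b <- numeric(1)
    bn$bn1 <- list(mean = numeric(1), var = rep(1, 1))
    bn$bn2 <- list(mean = numeric(f1), var = rep(1, f1))
  }
  if (use_ms) {
    for (i in 1:3) {
      k <- kernels[i]
      p[[paste0("msa", i, "_W")]] <- he_init(c(k, k, 1, f1), k * k)
      p[[paste0("msa", i, "_b")]] <- numeric(f1)
      p[[paste0("msb", i, "_W")]] <- he_init(c(3, 3, f1, f2), 9 * f1)
      p[[paste0("msb", i, "_b")]] <- numeric(f2)
    }
    p$msd1_W <- he_init(c(flat_ms, 256), flat_ms);    p$msd1_b <- numeric(256)
    p$msd2_W <- he_init(c(256, L), 256);              p$msd2_b <- numeric(L)
  }
  p$cls_W <- he_init(c(L, M), L)
  p$cls_b <- numeric(M)
  structure(list(cfg = cfg, input_dim = c(H, W), kernels = kernels,
                 use_ae = use_ae, use_ms = use_ms, params = p, bn = bn,
                 centers = matrix(0, M, L), scaler = NULL, version = "1"),
            class = "msaenet_model")
}

#' Build an ablation variant with its loss-weight overrides
#'
#' Applies the variant's structural changes through [build_model()] and
#' returns the adjusted loss weights: `multiscale` forces `beta1 = 0` (no
#' reconstruction target exists) and `withoutloss` forces `beta3 = 0`.
#'
#' @param cfg an [msaenet_config()] naming the variant.
#' @param weights base [loss_weights()].
#' @param input_dim optional `c(H, W)` (required for `rawdata`).
#' @param seed seed forwarded to [build_model()].
#' @return list with elements `model` and `weights`.
#' @export
make_variant <- function(cfg, weights = loss_weights(), input_dim = NULL,
                         seed = NULL) {
  stopifnot(inherits(cfg, "msaenet_config"))
  model <- build_model(cfg, input_dim = input_dim, seed = seed)
  w <- weights
  if (cfg$variant == "multiscale") w <- loss_weights(0, w$beta2, w$beta3)
  if (cfg$variant == "withoutloss") w <- loss_weights(w$beta1, w$beta2, 0)
  list(model = model, weights = w)
}

#' @export
print.msaenet_model <- function(x, ...) {
  cat(sprintf("msaenet_model (variant %s): input %d x %d, latent %d, %s\n",
              x$cfg$variant, x$input_dim[1], x$input_dim[2],
              x$cfg$latent_dim,
              paste0(format(count_params(x), big.mark = ","), " parameters")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution and dense weights, biases,
#' batch-norm scale/shift; running statistics and class centers excluded).
#'
#' @param model an `msaenet_model`.
#' @return integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# Full forward pass. Returns latent vectors (latent x B), reconstruction,
# probabilities (M x B) and the activation cache for the backward pass.
forward_msaenet <- function(model, x, training = FALSE) {
  p <- model$params
  d <- dim(x)
  if (d[1] != model$input_dim[1] || d[2] != model$input_dim[2]) {
    stop_invalid("input is ", d[1], " x ", d[2], " but the model expects ",
                 model$input_dim[1], " x ", model$input_dim[2])
  }
  B <- d[4]
  L <- model$cfg$latent_dim
  cache <- list(x = x)
  m <- NULL; z <- NULL; recon <- NULL
  if (model$use_ms) {
    f2 <- model$cfg$stage2_filters
    conv_f <- if (is.null(model$fmirror)) conv2d_fwd else conv2d_fwd_f32
    cc <- array(0, c(d[1], d[2], 3L * f2, B))
    for (i in 1:3) {
      a1 <- relu_inplace(conv_f(x, p[[paste0("msa", i, "_W")]],
                                p[[paste0("msa", i, "_b")]]))
      a2 <- relu_inplace(conv_f(a1, p[[paste0("msb", i, "_W")]],
                                p[[paste0("msb", i, "_b")]]))
      cc[, , (i - 1L) * f2 + seq_len(f2), ] <- a2
      cache[[paste0("ms_a1_", i)]] <- a1
      cache[[paste0("ms_a2_", i)]] <- a2
    }
    flat <- cc
    dim(flat) <- c(d[1] * d[2] * 3L * f2, B)
    h1 <- if (is.null(model$fmirror)) {
      dense_fwd(flat, p$msd1_W, p$msd1_b)
    } else {
      dense_fwd_f32(model$fmirror, nrow(p$msd1_W), ncol(p$msd1_W), flat,
                    p$msd1_b)
    }
    h1 <- relu_inplace(h1)
    m <- relu_inplace(dense_fwd(h1, p$msd2_W, p$msd2_b))
    cache$ms_flat <- flat
    cache$ms_h1 <- h1
    cache$m <- m
  }
  if (model$use_ae) {
    f1 <- model$cfg$stage1_filters
    r1 <- relu_inplace(conv2d_fwd(x, p$enc1_W, p$enc1_b))
    bn1 <- bn_fwd(r1, p$bn1_gamma, p$bn1_beta, model$bn$bn1, training)
    p1 <- avgpool2_fwd(bn1$y)
    r2 <- relu_inplace(conv2d_fwd(p1, p$enc2_W, p$enc2_b))
    bn2 <- bn_fwd(r2, p$bn2_gamma, p$bn2_beta, model$bn$bn2, training)
    p2 <- avgpool2_fwd(bn2$y)
    flat2 <- p2
    dim(flat2) <- c(length(p2) / B, B)
    z <- relu_inplace(dense_fwd(flat2, p$encz_W, p$encz_b))
    d1 <- relu_inplace(dense_fwd(z, p$dec1_W, p$dec1_b))
    rs <- d1 + 0
    dim(rs) <- c(d[1] %/% 4, d[2] %/% 4, f1, B)
    t1 <- relu_inplace(tconv2d_fwd(rs, p$tc1_W, p$tc1_b))
    recon <- relu_inplace(tconv2d_fwd(t1, p$tc2_W, p$tc2_b))
    cache <- c(cache, list(r1 = r1, bn1 = bn1, p1 = p1, r2 = r2, bn2 = bn2,
                           flat2 = flat2, z = z, d1 = d1, rs = rs, t1 = t1,
                           recon = recon))
    if (training) {
      model$bn$bn1 <- bn1$state
      model$bn$bn2 <- bn2$state
    }
  }
  fused <- if (model$use_ms && model$use_ae) m + z else (m %||% z)
  logits <- dense_fwd(fused, p$cls_W, p$cls_b)
  probs <- softmax_cols(logits)
  list(z = z, m = m, fused = fused, recon = recon, probs = probs,
       cache = cache, bn = model$bn)
}

# Batch losses for a forward pass: element-mean reconstruction MSE, mean
# cross-entropy and batch-mean center loss (the exported center_loss() keeps
# the batch-sum form; the optimizer uses the mean so gradients are
# batch-size invariant).
loss_batch <- function(model, fo, x, y, weights) {
  B <- ncol(fo$probs)
  l_mse <- if (model$use_ae) mean((fo$recon - x)^2) else 0
  pt <- fo$probs[cbind(y + 1L, seq_len(B))]
  l_ce <- mean(-log(pmax(pt, 1e-7)))
  diffs <- fo$fused - t(model$centers)[, y + 1L, drop = FALSE]
  l_center <- 0.5 * sum(diffs^2) / B
  total <- weights$beta1 * l_mse + weights$beta2 * l_ce +
    weights$beta3 * l_center
  if (!is.finite(total)) {
    bad <- c(mse = l_mse, cross_entropy = l_ce, center = l_center)
    stop_invalid("non-finite loss term: ",
                 paste(names(bad)[!is.finite(bad)], collapse = ", "))
  }
  list(mse = l_mse, ce = l_ce, center = l_center, total = total)
}

backward_msaenet <- function(model, fo, y, weights) {
  p <- model$params
  cache <- fo$cache
  x <- cache$x
  d <- dim(x)
  B <- ncol(fo$probs)
  M <- model$cfg$n_classes
  g <- list()
  Y <- matrix(0, M, B)
  Y[cbind(y + 1L, seq_len(B))] <- 1
  dlogits <- weights$beta2 * (fo$probs - Y) / B
  gc <- dense_bwd(fo$fused, p$cls_W, dlogits)
  g$cls_W <- gc$dW
  g$cls_b <- gc$db
  dfused <- gc$dx
  if (weights$beta3 > 0) {
    dfused <- dfused +
      weights$beta3 * (fo$fused - t(model$centers)[, y + 1L, drop = FALSE]) / B
  }
  if (model$use_ms) {
    f2 <- model$cfg$stage2_filters
    dm <- relu_grad_inplace(dfused + 0, cache$m)
    g2 <- dense_bwd(cache$ms_h1, p$msd2_W, dm)
    g$msd2_W <- g2$dW; g$msd2_b <- g2$db
    dh1 <- relu_grad_inplace(g2$dx, cache$ms_h1)
    g1 <- if (is.null(model$fmirror)) {
      dense_bwd(cache$ms_flat, p$msd1_W, dh1)
    } else {
      dense_bwd_f32(model$fmirror, nrow(p$msd1_W), ncol(p$msd1_W),
                    cache$ms_flat, dh1)
    }
    g$msd1_W <- g1$dW; g$msd1_b <- g1$db
    dcc <- g1$dx
    dim(dcc) <- c(d[1], d[2], 3L * f2, B)
    conv_b <- if (is.null(model$fmirror)) conv2d_bwd else conv2d_bwd_f32
    for (i in 1:3) {
      a1 <- cache[[paste0("ms_a1_", i)]]
      a2 <- cache[[paste0("ms_a2_", i)]]
      da2 <- relu_grad_inplace(
        dcc[, , (i - 1L) * f2 + seq_len(f2), , drop = FALSE], a2)
      gb <- conv_b(a1, p[[paste0("msb", i, "_W")]], da2, TRUE)
      g[[paste0("msb", i, "_W")]] <- gb$dw
      g[[paste0("msb", i, "_b")]] <- gb$db
      da1 <- relu_grad_inplace(gb$dx, a1)
      ga <- conv_b(x, p[[paste0("msa", i, "_W")]], da1, FALSE)
      g[[paste0("msa", i, "_W")]] <- ga$dw
      g[[paste0("msa", i, "_b")]] <- ga$db
    }
  }
  if (model$use_ae) {
    drecon <- weights$beta1 * 2 * (fo$recon - x) / length(x)
    drecon <- relu_grad_inplace(drecon, cache$recon)
    gt2 <- tconv2d_bwd(cache$t1, p$tc2_W, drecon)
    g$tc2_W <- gt2$dw; g$tc2_b <- gt2$db
    dt1 <- relu_grad_inplace(gt2$dx, cache$t1)
    gt1 <- tconv2d_bwd(cache$rs, p$tc1_W, dt1)
    g$tc1_W <- gt1$dw; g$tc1_b <- gt1$db
    dd1 <- gt1$dx
    dim(dd1) <- dim(cache$d1)
    dd1 <- relu_grad_inplace(dd1, cache$d1)
    gd <- dense_bwd(cache$z, p$dec1_W, dd1)
    g$dec1_W <- gd$dW; g$dec1_b <- gd$db
    dz <- relu_grad_inplace(dfused + gd$dx, cache$z)
    gz <- dense_bwd(cache$flat2, p$encz_W, dz)
    g$encz_W <- gz$dW; g$encz_b <- gz$db
    dp2 <- gz$dx
    dim(dp2) <- c(d[1] %/% 4, d[2] %/% 4, model$cfg$stage1_filters, B)
    db2 <- avgpool2_bwd(dp2)
    bb2 <- bn_bwd(db2, cache$r2, p$bn2_gamma, cache$bn2$cache)
    g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
    dc2 <- relu_grad_inplace(bb2$dx, cache$r2)
    ge2 <- conv2d_bwd(cache$p1, p$enc2_W, dc2, TRUE)
    g$enc2_W <- ge2$dw; g$enc2_b <- ge2$db
    db1 <- avgpool2_bwd(ge2$dx)
    bb1 <- bn_bwd(db1, cache$r1, p$bn1_gamma, cache$bn1$cache)
    g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
    dc1 <- relu_grad_inplace(bb1$dx, cache$r1)
    ge1 <- conv2d_bwd(x, p$enc1_W, dc1, FALSE)
    g$enc1_W <- ge1$dw; g$enc1_b <- ge1$db
  }
  g
}

#' Reconstruction mean-squared-error loss
#'
#' Mean over all elements of the squared difference between the input image
#' and its reconstruction (the per-channel-pair normalization generalized to
#' element count).
#'
#' @param x,xhat numeric arrays of identical shape.
#' @return scalar `>= 0`.
#' @export
mse_loss <- function(x, xhat) {
  if (!identical(dim(x) %||% length(x), dim(xhat) %||% length(xhat))) {
    stop_invalid("shape mismatch between x and xhat")
  }
  mean((x - xhat)^2)
}

#' Cross-entropy of a one-hot label against a probability vector
#'
#' `-sum_k y_k log(yhat_k)` with `yhat` clipped at `1e-7` before the log.
#'
#' @param y one-hot numeric vector of length M.
#' @param yhat probability vector of length M.
#' @param eps clipping floor.
#' @return scalar `>= 0`.
#' @export
cross_entropy <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stop_invalid("length mismatch")
  if (!all(y %in% c(0, 1)) || sum(y) != 1) {
    stop_invalid("y must be one-hot")
  }
  -sum(y * log(pmax(yhat, eps)))
}

#' Center loss of a batch of fused features
#'
#' `0.5 * sum_i || fused_i - c_{y_i} ||^2`, summed over the batch: the
#' intra-class compactness penalty attached to the softmax objective.
#'
#' @param fused `b x latent_dim` matrix, one row per sample.
#' @param labels integer class labels (0-based), length b.
#' @param centers `M x latent_dim` class-center matrix.
#' @return scalar `>= 0`.
#' @export
center_loss <- function(fused, labels, centers) {
  fused <- rbind(fused)
  if (ncol(fused) != ncol(centers)) stop_invalid("latent dimension mismatch")
  if (any(labels < 0) || any(labels >= nrow(centers))) {
    stop_invalid("labels outside 0..M-1")
  }
  diffs <- fused - centers[labels + 1L, , drop = FALSE]
  0.5 * sum(diffs^2)
}

#' Moving update of the class centers
#'
#' Non-gradient update applied after each optimizer step:
#' `c_y <- c_y - alpha * delta_y` with
#' `delta_y = sum_{i: y_i = y} (c_y - fused_i) / (1 + n_y)`. Classes absent
#' from the batch keep their centers.
#'
#' @param centers `M x latent_dim` matrix.
#' @param fused `b x latent_dim` matrix of fused features.
#' @param labels integer class labels (0-based), length b.
#' @param alpha update rate in `[0, 1]`.
#' @return the updated centers matrix.
#' @export
update_centers <- function(centers, fused, labels, alpha) {
  if (!is_number(alpha) || alpha < 0 || alpha > 1) {
    stop_invalid("alpha must be in [0, 1]")
  }
  fused <- rbind(fused)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n <- length(idx)
    delta <- colSums(matrix(centers[cl + 1L, ], n, ncol(centers),
                            byrow = TRUE) -
                     fused[idx, , drop = FALSE]) / (1 + n)
    centers[cl + 1L, ] <- centers[cl + 1L, ] - alpha * delta
  }
  centers
}

#' Weighted total loss
#'
#' `beta1 * l_mse + beta2 * l_ce + beta3 * l_center`, failing fast on
#' non-finite components.
#'
#' @param l_mse,l_ce,l_center scalar loss components.
#' @param weights a [loss_weights()].
#' @return scalar.
#' @export
total_loss <- function(l_mse, l_ce, l_center, weights = loss_weights()) {
  comps <- c(l_mse, l_ce, l_center)
  if (!all(is.finite(comps))) stop_invalid("non-finite loss component")
  weights$beta1 * l_mse + weights$beta2 * l_ce + weights$beta3 * l_center
}

# Forward pass in eval mode over mini-batches (memory-bounded).
forward_eval_batched <- function(model, images, batch = 128L) {
  N <- dim(images)[4]
  L <- model$cfg$latent_dim
  M <- model$cfg$n_classes
  probs <- matrix(0, M, N)
  fused <- matrix(0, L, N)
  for (at in seq(1L, N, by = batch)) {
    idx <- at:min(at + batch - 1L, N)
    fo <- forward_msaenet(model, images[, , , idx, drop = FALSE],
                          training = FALSE)
    probs[, idx] <- fo$probs
    fused[, idx] <- fo$fused
  }
  list(probs = probs, fused = fused)
}

#' Predict class labels for a batch of feature images
#'
#' @param object a trained `msaenet_model`.
#' @param images array `(H, W, 1, N)` matching the model input.
#' @param ... unused.
#' @return list with `labels` (0-based integers; ties broken toward the lower
#'   class index) and `probs` (`M x N` matrix of class probabilities).
#' @export
predict.msaenet_model <- function(object, images, ...) {
  fe <- forward_eval_batched(object, images)
  labels <- max.col(t(fe$probs), ties.method = "first") - 1L
  list(labels = labels, probs = fe$probs)
}

#' Save a model checkpoint
#'
#' Single-file, version-tagged archive (R serialization) holding the
#' configuration, parameters, batch-norm statistics, class centers, the
#' feature scaler and the loss weights used in training.
#'
#' @param model an `msaenet_model`.
#' @param path output file.
#' @param weights optional [loss_weights()] stored alongside.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, weights = NULL) {
  saveRDS(list(format = "midecode-checkpoint", version = model$version,
               cfg = model$cfg, input_dim = model$input_dim,
               kernels = model$kernels, params = model$params, bn = model$bn,
               centers = model$centers, scaler = model$scaler,
               weights = weights),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_model()].
#' @return list with `model` (an `msaenet_model`) and `weights` (the stored
#'   [loss_weights()] or `NULL`).
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "midecode-checkpoint")) {
    stop_invalid("not a midecode checkpoint: ", path)
  }
  model <- structure(
    list(cfg = ck$cfg, input_dim = ck$input_dim, kernels = ck$kernels,
         use_ae = ck$cfg$variant != "multiscale",
         use_ms = ck$cfg$variant != "ae",
         params = ck$params, bn = ck$bn, centers = ck$centers,
         scaler = ck$scaler, version = ck$version),
    class = "msaenet_model")
  list(model = model, weights = ck$weights)
}
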