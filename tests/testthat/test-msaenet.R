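test_that("loss terms match their closed forms and independent oracles", {
  set.seed(21)
  x <- array(runif(9), c(3, 3, 1))
  expect_equal(mse_loss(x, x), 0)
  expect_equal(mse_loss(x, x + 1), 1)
  xh <- array(runif(9), c(3, 3, 1))
  direct <- sum((x - xh)^2) / 9          # elementwise double-sum oracle
  expect_equal(mse_loss(x, xh), direct, tolerance = 1e-12)
  expect_error(mse_loss(x, array(0, c(2, 2, 1))), "shape")

  expect_lte(cross_entropy(c(1, 0), c(1, 0)), 1e-6)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-12)
  for (i in 1:5) {
    p <- runif(4); p <- p / sum(p)
    y <- as.numeric(seq_len(4) == sample(4, 1))
    expect_equal(cross_entropy(y, p), -sum(y * log(p)), tolerance = 1e-10)
  }
  expect_error(cross_entropy(c(1, 1), c(0.5, 0.5)), "one-hot")

  centers <- matrix(rnorm(2 * 5), 2, 5)
  fused <- centers[c(1, 2, 1) , ]
  expect_equal(center_loss(fused, c(0L, 1L, 0L), centers), 0)
  e1 <- matrix(c(1, rep(0, 4)), 1)
  expect_equal(center_loss(e1, 0L, matrix(0, 2, 5)), 0.5)
  fb <- matrix(rnorm(4 * 5), 4)
  lb <- c(0L, 1L, 1L, 0L)
  direct <- 0.5 * sum((fb - centers[lb + 1, ])^2)
  expect_equal(center_loss(fb, lb, centers), direct, tolerance = 1e-12)
})

test_that("total loss is the weighted sum and linear in each weight", {
  w <- loss_weights(0.5, 1.0, 0.5)
  expect_equal(total_loss(2, 3, 4, w), 6.0)
  expect_equal(total_loss(1, 1, 1, loss_weights(0, 0, 0)), 0)
  expect_equal(total_loss(7, 3, 9, loss_weights(1, 0, 0)), 7)
  set.seed(22)
  for (i in 1:5) {
    comp <- runif(3, 0, 5)
    b <- runif(3)
    base <- total_loss(comp[1], comp[2], comp[3], loss_weights(b[1], b[2], b[3]))
    for (k in 1:3) {
      b2 <- b; b2[k] <- 2 * b[k]
      up <- total_loss(comp[1], comp[2], comp[3],
                       loss_weights(b2[1], b2[2], b2[3]))
      expect_equal(up - base, b[k] * comp[k], tolerance = 1e-12)
    }
  }
  expect_error(total_loss(Inf, 0, 0, w), "non-finite")
})

test_that("center update follows the damped moving rule", {
  centers <- matrix(c(1, 2, 3, 4), 2, 2)
  fused <- matrix(rnorm(6), 3, 2)
  lb <- c(0L, 0L, 1L)
  expect_identical(update_centers(centers, fused, lb, 0), centers)
  # alpha = 1, one sample: center moves to the midpoint
  x <- c(5, 5)
  up <- update_centers(centers, matrix(x, 1), 0L, 1)
  expect_equal(up[1, ], (centers[1, ] + x) / 2)
  expect_equal(up[2, ], centers[2, ])  # absent class untouched
  # general rule oracle
  a <- 0.3
  up2 <- update_centers(centers, fused, lb, a)
  d0 <- colSums(matrix(centers[1, ], 2, 2, byrow = TRUE) -
                fused[1:2, ]) / 3
  expect_equal(up2[1, ], centers[1, ] - a * d0, tolerance = 1e-12)
})

test_that("the built architecture honours the documented geometry", {
  m <- build_model(msaenet_config(), seed = 1)
  x <- array(runif(28 * 28 * 2), c(28, 28, 1, 2))
  fo <- midecode:::forward_msaenet(m, x)
  expect_length(fo$z[, 1], 20)
  expect_length(fo$m[, 1], 20)
  expect_equal(dim(fo$recon), c(28, 28, 1, 2))
  expect_equal(fo$fused, fo$m + fo$z)
  expect_true(all(fo$probs >= 0))
  expect_equal(colSums(fo$probs), c(1, 1), tolerance = 1e-6)
  m16 <- build_model(msaenet_config(input_size = 16), seed = 1)
  x16 <- array(runif(16 * 16), c(16, 16, 1, 1))
  fo16 <- midecode:::forward_msaenet(m16, x16)
  expect_equal(dim(fo16$recon), c(16, 16, 1, 1))
  expect_error(build_model(msaenet_config(input_size = 27)), "divisible by 4")
})

test_that("ablation variants change exactly what they claim to change", {
  w <- loss_weights(0.5, 1.0, 0.5)
  ss <- make_variant(msaenet_config(input_size = 12, variant = "singlescale"),
                     w, seed = 1)
  expect_equal(ss$model$kernels, c(3L, 3L, 3L))
  expect_equal(dim(ss$model$params$msa2_W)[1], 3)
  wl <- make_variant(msaenet_config(input_size = 12, variant = "withoutloss"),
                     w, seed = 1)
  expect_equal(wl$weights$beta3, 0)
  expect_equal(wl$weights$beta1, 0.5)
  expect_equal(wl$weights$beta2, 1.0)
  ms <- make_variant(msaenet_config(input_size = 12, variant = "multiscale"),
                     w, seed = 1)
  expect_equal(ms$weights$beta1, 0)
  x <- array(runif(12 * 12 * 2), c(12, 12, 1, 2))
  fo <- midecode:::forward_msaenet(ms$model, x)
  expect_null(fo$recon)
  expect_equal(fo$fused, fo$m)
  ae <- make_variant(msaenet_config(input_size = 12, variant = "ae"), w,
                     seed = 1)
  fo_ae <- midecode:::forward_msaenet(ae$model, x)
  expect_null(fo_ae$m)
  expect_equal(fo_ae$fused, fo_ae$z)
  expect_error(msaenet_config(variant = "nope"))
})

test_that("prediction breaks probability ties toward the lower class", {
  m <- build_model(msaenet_config(input_size = 8, latent_dim = 4), seed = 2)
  m$params$cls_W[] <- 0
  m$params$cls_b[] <- 0
  x <- array(runif(8 * 8 * 3), c(8, 8, 1, 3))
  pr <- predict(m, x)
  expect_equal(pr$probs[1, ], rep(0.5, 3))
  expect_equal(pr$labels, rep(0L, 3))
  expect_length(predict(m, x)$labels, 3)
})

test_that("backpropagation matches finite differences for every tensor", {
  set.seed(23)
  model <- build_model(msaenet_config(input_size = 8, latent_dim = 3),
                       seed = 31)
  # move to a generic parameter point: zero-initialized biases can leave
  # activations exactly at the ReLU kink, where no subgradient matches a
  # central difference
  model$params <- lapply(model$params, function(p) {
    q <- p + rnorm(length(p), sd = 0.05)
    dim(q) <- dim(p)
    q
  })
  B <- 3
  x <- array(runif(8 * 8 * B), c(8, 8, 1, B))
  y <- c(0L, 1L, 0L)
  model$centers <- matrix(rnorm(6), 2, 3)
  w <- loss_weights(0.5, 1.0, 0.5)
  lossfun <- function(m) {
    fo <- midecode:::forward_msaenet(m, x, training = TRUE)
    midecode:::loss_batch(m, fo, x, y, w)$total
  }
  fo <- midecode:::forward_msaenet(model, x, training = TRUE)
  g <- midecode:::backward_msaenet(model, fo, y, w)
  eps <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(5, length(p)))) {
      m2 <- model
      m2$params[[nm]] <- p + 0
      m2$params[[nm]][i] <- p[i] + eps
      lp <- lossfun(m2)
      m2$params[[nm]][i] <- p[i] - eps
      lm <- lossfun(m2)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - g[[nm]][i]) / max(1e-6, abs(fd), abs(g[[nm]][i])),
                1e-4)
    }
  }
})

test_that("checkpoints round-trip the model and its training state", {
  m <- build_model(msaenet_config(input_size = 12), seed = 3)
  m$centers <- matrix(rnorm(40), 2, 20)
  path <- tempfile(fileext = ".rds")
  save_model(m, path, weights = loss_weights())
  back <- load_model(path)
  expect_identical(back$model$params, m$params)
  expect_identical(back$model$centers, m$centers)
  expect_equal(back$weights$beta2, 1.0)
  x <- array(runif(12 * 12), c(12, 12, 1, 1))
  expect_identical(predict(m, x)$probs, predict(back$model, x)$probs)
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "not a midecode checkpoint")
  unlink(c(path, other))
})

test_that("trainable parameter count tracks the architecture", {
  m <- build_model(msaenet_config(), seed = 1)
  n28 <- count_params(m)
  m12 <- build_model(msaenet_config(input_size = 12), seed = 1)
  expect_gt(n28, count_params(m12))
  # hand count of the classifier head
  expect_equal(length(m$params$cls_W) + length(m$params$cls_b), 20 * 2 + 2)
})
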