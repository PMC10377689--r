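test_that("class covariance is trace-normalized and consistent", {
  tr <- tiny_trials(N = 6, C = 4, Tn = 500, seed = 2)
  S <- class_covariance(tr, 0)
  expect_equal(sum(diag(S)), 1, tolerance = 1e-10)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_error(class_covariance(tr, 5), "no trials")
})

test_that("independent channels give a near-diagonal covariance at large T", {
  set.seed(11)
  tr <- epoched_trials(array(rnorm(1 * 3 * 1e4), c(1, 3, 1e4)), 0L, 250)
  S <- class_covariance(tr, 0)
  off <- S - diag(diag(S))
  expect_lt(max(abs(off)) / mean(diag(S)), 0.05)
})

test_that("a duplicated channel produces a rank-deficient covariance", {
  set.seed(12)
  x <- rnorm(1000)
  X <- array(0, c(1, 3, 1000))
  X[1, 1, ] <- x; X[1, 2, ] <- x; X[1, 3, ] <- rnorm(1000)
  tr <- epoched_trials(X, 0L, 250)
  S <- class_covariance(tr, 0)
  expect_equal(S[1, 2] / sqrt(S[1, 1] * S[2, 2]), 1, tolerance = 1e-10)
  expect_lt(min(eigen(S, symmetric = TRUE)$values), 1e-10)
})

test_that("CSP recovers a constructed axis-aligned contrast", {
  sd0 <- c(sqrt(2), 1)
  sd1 <- c(1, sqrt(2))
  tr <- diag_cov_trials(sd0, sd1, n_per_class = 60, Tn = 4000, seed = 13)
  bank <- fit_csp(tr)
  expect_equal(bank$eigenvalues, c(2 / 3, 1 / 3), tolerance = 0.03)
  # first filter aligned with axis 1, last with axis 2 (up to sign/scale)
  cosang <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosang(bank$W[1, ], c(1, 0)), 0.98)
  expect_gt(cosang(bank$W[2, ], c(0, 1)), 0.98)
})

test_that("identical class distributions give eigenvalues near one half", {
  tr <- diag_cov_trials(c(1, 1, 1), c(1, 1, 1), n_per_class = 100,
                        Tn = 1000, seed = 14)
  bank <- fit_csp(tr)
  expect_true(all(abs(bank$eigenvalues - 0.5) < 0.05))
})

test_that("fitted filters match the generalized-eigenvector oracle", {
  set.seed(15)
  for (rep in 1:10) {
    C <- sample(2:8, 1)
    A0 <- matrix(rnorm(C * C), C); S0 <- crossprod(A0) + diag(C) * 0.1
    A1 <- matrix(rnorm(C * C), C); S1 <- crossprod(A1) + diag(C) * 0.1
    N <- 8
    X <- array(0, c(2 * N, C, 400))
    y <- rep(0:1, each = N)
    for (i in seq_len(2 * N)) {
      S <- if (y[i] == 0) S0 else S1
      X[i, , ] <- t(chol(S)) %*% matrix(rnorm(C * 400), C)
    }
    tr <- epoched_trials(X, y, 250)
    bank <- fit_csp(tr, shrinkage = 0)
    E0 <- bank$class_covs[[1]]
    E1 <- bank$class_covs[[2]]
    oracle <- eigen(solve(E0 + E1) %*% E0)
    for (u in seq_len(C)) {
      # CSP rows are generalized eigenvectors of (S0, S0+S1), i.e. ordinary
      # eigenvectors of (S0+S1)^-1 S0 — the oracle route
      w <- bank$W[u, ]
      v <- Re(oracle$vectors[, u])
      cosd <- 1 - abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
      expect_lt(cosd, 1e-6)
    }
    M <- bank$W %*% (E0 + E1) %*% t(bank$W)
    expect_lt(max(abs(M - diag(C))), 1e-8)
  }
})

test_that("covariance features reduce to the sample covariance for W = I", {
  tr <- tiny_trials(N = 1, C = 3, Tn = 200, seed = 16)
  bank <- list(W = diag(3))
  Cp <- covariance_feature(tr$X[1, , ], bank)
  expect_equal(Cp, cov(t(tr$X[1, , ])), tolerance = 1e-12)
  # hand-computed toy case with the unbiased estimator
  E <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  Cp2 <- covariance_feature(E, list(W = diag(2)))
  expect_equal(Cp2, matrix(c(4 / 3, 0, 0, 4 / 3), 2), tolerance = 1e-12)
  expect_equal(Cp, t(Cp), tolerance = 1e-10)
  expect_error(covariance_feature(E, list(W = diag(3))), "channels")
})

test_that("feature images scale with the training scaler and pad with zeros", {
  set.seed(17)
  covs <- replicate(5, {
    A <- matrix(rnorm(16), 4)
    crossprod(A)
  }, simplify = FALSE)
  scaler <- fit_feature_scaler(covs)
  img <- to_feature_image(covs[[1]], 7, scaler)
  expect_equal(dim(img$values), c(7, 7, 1))
  expect_true(all(img$values[5:7, , 1] == 0))
  expect_true(all(img$values[, 5:7, 1] == 0))
  expect_true(all(img$values >= 0 & img$values <= 1))
  # constant at the training minimum maps to all-zero embedded block
  cmin <- matrix(scaler$min, 4, 4)
  expect_true(all(to_feature_image(cmin, 7, scaler)$values == 0))
  # no padding when U = target
  expect_equal(dim(to_feature_image(covs[[1]], 4, scaler)$values),
               c(4, 4, 1))
  expect_error(to_feature_image(covs[[1]], 3, scaler), "must be >= U")
})

test_that("scaler statistics depend on training data only", {
  spec <- cohort_spec(n_subjects = 2, trials_per_class = 10, seed = 18)
  cohort <- generate_cohort(spec)
  f1 <- prepare_fold_features(cohort[[1]], cohort[[2]], target_size = 12)
  mutated <- cohort[[2]]
  mutated$X <- mutated$X * 5 + 1
  f2 <- prepare_fold_features(cohort[[1]], mutated, target_size = 12)
  expect_identical(f1$scaler, f2$scaler)
  expect_identical(f1$bank$W, f2$bank$W)
  expect_identical(f1$x_train, f2$x_train)
  expect_false(identical(f1$x_test, f2$x_test))
})

test_that("the first CSP component discriminates better than any raw channel", {
  for (seed in 1:3) {
    spec <- cohort_spec(n_subjects = 2, trials_per_class = 40,
                        class_contrast = 0.8, seed = 30 + seed)
    tr <- bandpass_trials(generate_subject(spec, 0))
    bank <- fit_csp(tr)
    var_ratio <- function(v0, v1) max(v0 / v1, v1 / v0)
    proj_var <- function(i, w) {
      var(as.vector(w %*% tr$X[i, , ]))
    }
    csp_v0 <- mean(vapply(which(tr$y == 0), proj_var, 0, w = bank$W[1, , drop = FALSE]))
    csp_v1 <- mean(vapply(which(tr$y == 1), proj_var, 0, w = bank$W[1, , drop = FALSE]))
    csp_ratio <- var_ratio(csp_v0, csp_v1)
    raw_ratios <- vapply(seq_len(dim(tr$X)[2]), function(ch) {
      v0 <- mean(apply(tr$X[tr$y == 0, ch, ], 1, var))
      v1 <- mean(apply(tr$X[tr$y == 1, ch, ], 1, var))
      var_ratio(v0, v1)
    }, 0)
    expect_gt(csp_ratio, max(raw_ratios))
  }
})

test_that("a singular composite covariance asks for regularization", {
  set.seed(19)
  x <- rnorm(500)
  X <- array(0, c(4, 2, 500))
  for (i in 1:4) {
    X[i, 1, ] <- x * i
    X[i, 2, ] <- x * i   # perfectly collinear channels
  }
  tr <- epoched_trials(X, c(0L, 0L, 1L, 1L), 250)
  expect_error(fit_csp(tr, shrinkage = 0), "regularization")
  # default shrinkage handles it
  expect_s3_class(fit_csp(tr), "spatial_filter_bank")
})
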