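# Shared fixtures. Everything is generated in code; nothing is read from disk.

# Tiny epoched-trials object with known geometry.
tiny_trials <- function(N = 4, C = 3, Tn = 100, fs = 250, seed = 1,
                        channel_names = NULL) {
  set.seed(seed)
  epoched_trials(array(rnorm(N * C * Tn), c(N, C, Tn)),
                 y = rep(0:1, length.out = N), fs = fs,
                 channel_names = channel_names)
}

# Trials whose two classes have prescribed diagonal channel covariances.
diag_cov_trials <- function(sd0, sd1, n_per_class = 50, Tn = 2000, fs = 250,
                            seed = 1) {
  set.seed(seed)
  C <- length(sd0)
  N <- 2L * n_per_class
  X <- array(0, c(N, C, Tn))
  y <- rep(0:1, each = n_per_class)
  for (i in seq_len(N)) {
    s <- if (y[i] == 0) sd0 else sd1
    X[i, , ] <- s * matrix(rnorm(C * Tn), C, Tn)
  }
  epoched_trials(X, y, fs)
}

# The 22-channel montage used by the public four-class MI dataset.
montage22 <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C5", "C3", "C1", "Cz", "C2",
    "C4", "C6", "CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz", "P2", "POz")
}

# Pure-sine trials for filter-response checks (both channels identical).
sine_trials <- function(freq, fs = 250, dur = 4) {
  tt <- (seq_len(fs * dur) - 1) / fs
  s <- sin(2 * pi * freq * tt)
  epoched_trials(array(rep(s, each = 2), c(1, 2, length(s))),
                 y = 0L, fs = fs)
}

rms <- function(x) sqrt(mean(x^2))

# CSP log-variance (first + last filter) + linear read-out, the independent
# separability oracle used for the synthetic generator.
csp_linear_accuracy <- function(train, test, band = bandpass_spec()) {
  trf <- bandpass_trials(train, band)
  tef <- bandpass_trials(test, band)
  bank <- fit_csp(trf)
  featf <- function(tr) {
    t(vapply(seq_len(dim(tr$X)[1]), function(i) {
      v <- diag(covariance_feature(tr$X[i, , ], bank))
      log(v[c(1, length(v))])
    }, numeric(2)))
  }
  df <- data.frame(featf(trf), y = trf$y)
  # perfect separation is expected by construction; silence the glm note
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = df))
  pr <- as.integer(suppressWarnings(
    predict(fit, data.frame(featf(tef)), type = "response")) > 0.5)
  100 * mean(pr == tef$y)
}
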