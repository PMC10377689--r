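#' Class-conditional average channel covariance
#'
#' Each trial's unbiased sample covariance over time is trace-normalized
#' (making the estimate invariant to per-trial amplitude scale, standard CSP
#' practice for cross-subject work), then averaged over the class. The result
#' has unit trace.
#'
#' @param trials an `epoched_trials` object.
#' @param class_label integer class label present in `trials$y`.
#' @return a `C x C` symmetric positive semi-definite matrix with trace 1.
#' @export
class_covariance <- function(trials, class_label) {
  validate_trials(trials)
  idx <- which(trials$y == class_label)
  if (length(idx) == 0L) stop_invalid("no trials with class ", class_label)
  C <- dim(trials$X)[2]
  acc <- matrix(0, C, C)
  for (i in idx) {
    S <- cov(t(trials$X[i, , ]))
    acc <- acc + S / sum(diag(S))
  }
  acc / length(idx)
}

shrink_cov <- function(S, gamma) {
  C <- nrow(S)
  (1 - gamma) * S + gamma * (sum(diag(S)) / C) * diag(C)
}

#' Fit common spatial patterns on two-class trials
#'
#' Solves the simultaneous diagonalization of the class covariances: filters
#' `W` (rows) whiten the composite covariance, `W (S0 + S1) W' = I`, and
#' diagonalize the class-0 covariance, `W S0 W' = diag(lambda)` with
#' eigenvalues in (0, 1) sorted descending. The first filters maximize class-0
#' variance relative to class 1 and the last minimize it. All `U = C` filters
#' are retained so the downstream covariance feature is a full square image.
#' Each filter is sign-fixed so its largest-magnitude coefficient is positive.
#'
#' @param trials an `epoched_trials` object containing exactly two classes.
#' @param shrinkage shrinkage weight `gamma` toward the scaled identity,
#'   guarding rank deficiency after channel selection.
#' @return an object of class `spatial_filter_bank` with elements `W`
#'   (`U x C`), `eigenvalues`, `class_covs` (list of the two unit-trace class
#'   covariances) and `U`.
#' @export
fit_csp <- function(trials, shrinkage = 1e-6) {
  validate_trials(trials, require_two_classes = TRUE)
  classes <- sort(unique(trials$y))
  if (length(classes) != 2L) {
    stop_invalid("CSP supports exactly two classes, found ",
                 length(classes))
  }
  S0 <- shrink_cov(class_covariance(trials, classes[1]), shrinkage)
  S1 <- shrink_cov(class_covariance(trials, classes[2]), shrinkage)
  Sc <- S0 + S1
  ec <- eigen(Sc, symmetric = TRUE)
  if (min(ec$values) <= 1e-12 * max(ec$values)) {
    stop_invalid("composite covariance is singular; increase the ",
                 "`shrinkage` regularization or remove redundant channels")
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitening
  M <- P %*% S0 %*% t(P)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)      # descending by default
  W <- t(em$vectors) %*% P
  for (i in seq_len(nrow(W))) {
    if (W[i, which.max(abs(W[i, ]))] < 0) W[i, ] <- -W[i, ]
  }
  structure(list(W = W, eigenvalues = em$values,
                 class_covs = list(S0, S1), U = nrow(W)),
            class = "spatial_filter_bank")
}

#' Spatial-spectral covariance feature of one trial
#'
#' Projects the band-passed trial through the CSP filters and returns the
#' unbiased sample covariance of the projected signal over time, the `U x U`
#' feature matrix fed to the network.
#'
#' @param trial a `C x T` signal matrix (one trial).
#' @param bank a fitted [fit_csp()] bank (or any object with a `W` matrix).
#' @return a `U x U` symmetric matrix.
#' @export
covariance_feature <- function(trial, bank) {
  W <- bank$W
  if (ncol(W) != nrow(trial)) {
    stop_invalid("trial has ", nrow(trial), " channels but the filter bank ",
                 "expects ", ncol(W))
  }
  Z <- W %*% trial
  cov(t(Z))
}

#' Fit the feature-image min/max scaler
#'
#' Computes the global minimum and maximum over all entries of the training
#' covariance features. The scaler must be fitted on training-fold data only;
#' test images reuse it unchanged (values are clipped into `[0, 1]`).
#'
#' @param covs list of `U x U` covariance matrices from the training fold.
#' @return an object of class `feature_scaler` with `min` and `max`.
#' @export
fit_feature_scaler <- function(covs) {
  vals <- range(unlist(lapply(covs, range)))
  if (!all(is.finite(vals))) stop_invalid("non-finite covariance features")
  structure(list(min = vals[1], max = vals[2]), class = "feature_scaler")
}

#' Embed a covariance feature into a fixed-size network input image
#'
#' Linearly rescales the `U x U` matrix to `[0, 1]` with the training-fold
#' scaler (clipping out-of-range test values), then zero-pads at the bottom
#' and right to `target x target`.
#'
#' @param cov a `U x U` covariance matrix.
#' @param target output image side (`>= U`).
#' @param scaler a [fit_feature_scaler()] result.
#' @return an object of class `feature_image`: list with `values`
#'   (`target x target x 1` array in `[0, 1]`), `raw_cov`, and `source_trial`
#'   (`NA` unless set by the caller).
#' @export
to_feature_image <- function(cov, target, scaler) {
  U <- nrow(cov)
  if (target < U) stop_invalid("target (", target, ") must be >= U (", U, ")")
  rng <- scaler$max - scaler$min
  scaled <- if (rng <= 0) matrix(0, U, U) else (cov - scaler$min) / rng
  scaled <- pmin(pmax(scaled, 0), 1)
  img <- array(0, c(target, target, 1))
  img[seq_len(U), seq_len(U), 1] <- scaled
  structure(list(values = img, raw_cov = cov, source_trial = NA_integer_),
            class = "feature_image")
}

#' Convert epoched trials to a batch of network input images
#'
#' Maps every trial through [covariance_feature()] and [to_feature_image()],
#' returning the `(target, target, 1, N)` tensor the network consumes.
#'
#' @param trials an `epoched_trials` object (already band-passed).
#' @param bank a fitted [fit_csp()] bank.
#' @param target image side.
#' @param scaler a [fit_feature_scaler()] result.
#' @return numeric array `(target, target, 1, N)`.
#' @export
trials_to_images <- function(trials, bank, target, scaler) {
  N <- n_trials(trials)
  out <- array(0, c(target, target, 1, N))
  for (i in seq_len(N)) {
    fi <- to_feature_image(covariance_feature(trials$X[i, , ], bank),
                           target, scaler)
    out[, , , i] <- fi$values
  }
  out
}

covariance_features <- function(trials, bank) {
  lapply(seq_len(n_trials(trials)),
         function(i) covariance_feature(trials$X[i, , ], bank))
}
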