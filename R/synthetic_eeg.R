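#' Specification of a synthetic motor-imagery EEG cohort
#'
#' Defines a multi-subject, two-class cohort of epoched EEG with known
#' class-dependent spatial structure. Two narrow-band oscillatory sources (a
#' mu-band and a beta-band rhythm) are mixed into the channels through a
#' subject-specific mixing matrix and buried in 1/f background noise. Class
#' differences follow an ERD-like rule: class 0 attenuates the mu source and
#' class 1 attenuates the beta source, both by `class_contrast`.
#'
#' The defaults describe the conditions used throughout the package's test
#' suite: a small 8-channel sensorimotor montage, 0.75-s epochs at 64 Hz
#' (about seven mu cycles, ample for covariance estimation of stationary
#' narrow-band sources), 20 trials per class and subject, contrast 0.8,
#' source-to-noise power ratio 5 and moderate between-subject mixing
#' variability 0.3.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param trials_per_class trials per class and subject (>= 1).
#' @param n_channels number of EEG channels (>= 2).
#' @param fs sampling rate, Hz.
#' @param duration epoch length, seconds.
#' @param mu_freq,beta_freq source center frequencies, Hz
#'   (`0 < mu_freq < beta_freq < fs/2`).
#' @param class_contrast amplitude attenuation depth in `[0, 1]` applied to the
#'   class-specific source (0 = classes identical).
#' @param snr source-to-noise power ratio (> 0).
#' @param subject_sigma std of the additive per-subject mixing perturbation
#'   (>= 0, scale-free: entries are perturbed with sd
#'   `subject_sigma / sqrt(n_channels)`).
#' @param seed integer base seed; all randomness is derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 6, trials_per_class = 20, n_channels = 8,
                        fs = 64, duration = 0.75, mu_freq = 10, beta_freq = 22,
                        class_contrast = 0.8, snr = 5, subject_sigma = 0.3,
                        seed = 1) {
  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         trials_per_class = as.integer(trials_per_class),
         n_channels = as.integer(n_channels), fs = fs, duration = duration,
         mu_freq = mu_freq, beta_freq = beta_freq,
         class_contrast = class_contrast, snr = snr,
         subject_sigma = subject_sigma, seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (!is_count(spec$n_subjects, 2L)) stop_invalid("n_subjects must be >= 2")
  if (!is_count(spec$trials_per_class, 1L)) {
    stop_invalid("trials_per_class must be >= 1")
  }
  if (!is_count(spec$n_channels, 2L)) stop_invalid("n_channels must be >= 2")
  if (!is_number(spec$fs) || spec$fs <= 0) stop_invalid("fs must be > 0")
  if (!is_number(spec$duration) || spec$duration <= 0) {
    stop_invalid("duration must be > 0")
  }
  if (!(is_number(spec$mu_freq) && is_number(spec$beta_freq) &&
        spec$mu_freq > 0 && spec$mu_freq < spec$beta_freq &&
        spec$beta_freq < spec$fs / 2)) {
    stop_invalid("need 0 < mu_freq < beta_freq < fs/2")
  }
  if (!is_number(spec$class_contrast) || spec$class_contrast < 0 ||
      spec$class_contrast > 1) {
    stop_invalid("class_contrast must be in [0, 1]")
  }
  if (!is_number(spec$snr) || spec$snr <= 0) stop_invalid("snr must be > 0")
  if (!is_number(spec$subject_sigma) || spec$subject_sigma < 0) {
    stop_invalid("subject_sigma must be >= 0")
  }
  invisible(spec)
}

# Cohort-level source model: smooth spatial topographies (Gaussian bumps over
# the channel axis, one centered left, one right) plus a small random
# component that guarantees full column rank.
source_model <- function(spec) {
  C <- spec$n_channels
  set.seed(child_seed(spec$seed, 0, 0))
  ch <- seq_len(C)
  bump <- function(center, width) exp(-((ch - center)^2) / (2 * width^2))
  A <- cbind(bump(0.3 * C, C / 4), bump(0.7 * C, C / 4)) +
    0.25 * matrix(rnorm(2 * C), C, 2)
  if (qr(A)$rank < 2L) {       # practically unreachable; keeps the invariant
    A <- A + diag(1, C, 2)
  }
  list(base_mixing = A,
       source_bands = list(c(spec$mu_freq, 4), c(spec$beta_freq, 4)),
       class_gain = rbind(`0` = c(1 - spec$class_contrast, 1),
                          `1` = c(1, 1 - spec$class_contrast)))
}

# Narrow-band source: white noise band-passed +-2 Hz around the center
# frequency (4th-order Butterworth, zero-phase), normalized to unit sd.
narrowband_source <- function(n, fs, center) {
  lo <- max(center - 2, 0.5)
  hi <- min(center + 2, 0.499 * fs)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  pad <- min(3L * fs, n)
  x <- rnorm(n + 2L * pad)
  x <- filtfilt_padded(bf, x)[pad + seq_len(n)]
  x / max(sd(x), .Machine$double.eps)
}

# 1/f-amplitude background noise synthesized in the frequency domain with
# random phases, independent per channel, unit sd.
pink_noise <- function(n) {
  nf <- n %/% 2L
  amp <- 1 / sqrt(seq_len(nf))
  phase <- runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  spec <- complex(n)
  spec[2:(nf + 1L)] <- half
  spec[n:(n - nf + 2L)] <- Conj(half[seq_len(nf - 1L)])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / max(sd(x), .Machine$double.eps)
}

#' Generate one synthetic subject
#'
#' Deterministic given `(spec$seed, subject_index)`: every trial draws from its
#' own derived RNG stream, so a subject's data do not depend on cohort size or
#' on the order of generation.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 0-based subject index (`< n_subjects`).
#' @return an `epoched_trials` object with `2 * trials_per_class` trials
#'   (labels balanced, class 0 first) and `subject_id = subject_index`.
#' @export
generate_subject <- function(spec, subject_index) {
  validate_cohort_spec(spec)
  if (!is_count(subject_index, 0L) || subject_index >= spec$n_subjects) {
    stop_invalid("subject_index must be in 0..n_subjects-1")
  }
  model <- source_model(spec)
  C <- spec$n_channels
  Tn <- round(spec$fs * spec$duration)
  set.seed(child_seed(spec$seed, subject_index + 1L, 0))
  A <- model$base_mixing +
    (spec$subject_sigma / sqrt(C)) * matrix(rnorm(2 * C), C, 2)
  K <- spec$trials_per_class
  X <- array(0, c(2L * K, C, Tn))
  y <- rep(0:1, each = K)
  for (i in seq_len(2L * K)) {
    set.seed(child_seed(spec$seed, subject_index + 1L, i))
    gain <- model$class_gain[y[i] + 1L, ]
    S <- rbind(gain[1] * narrowband_source(Tn, spec$fs, spec$mu_freq),
               gain[2] * narrowband_source(Tn, spec$fs, spec$beta_freq))
    sig <- A %*% S
    noise <- t(vapply(seq_len(C), function(ch) pink_noise(Tn), numeric(Tn)))
    noise_scale <- sqrt(mean(sig^2) / spec$snr)
    X[i, , ] <- sig + noise_scale * noise
  }
  epoched_trials(X, y, spec$fs, sprintf("SYN%02d", seq_len(C)),
                 subject_id = subject_index)
}

#' Generate a synthetic cohort
#'
#' All subjects share the cohort-level mixing topographies but receive
#' independent per-subject perturbations of magnitude `subject_sigma`.
#'
#' @param spec a [cohort_spec()].
#' @return a list of `epoched_trials`, one per subject, with subject ids
#'   `0..n_subjects-1`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  lapply(seq_len(spec$n_subjects) - 1L, function(s) generate_subject(spec, s))
}
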