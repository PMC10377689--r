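#' Band-pass filter specification
#'
#' Order and corner frequencies of the Butterworth band-pass applied before
#' CSP. The defaults (8-30 Hz, order 5) cover the mu and beta rhythms that
#' carry motor-imagery information.
#'
#' @param low,high corner frequencies in Hz (`0 < low < high`, and
#'   `high < fs/2` at application time).
#' @param order filter order (>= 1).
#' @return an object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low = 8, high = 30, order = 5) {
  if (!is_number(low) || !is_number(high) || low <= 0 || high <= low) {
    stop_invalid("need 0 < low < high")
  }
  if (!is_count(order, 1L)) stop_invalid("order must be >= 1")
  structure(list(low = low, high = high, order = as.integer(order)),
            class = "bandpass_spec")
}

# Zero-phase filtering with odd-reflection edge padding (signal::filtfilt has
# no internal padding, which leaves large transients on signals with offset).
# The pad is generous (30 filter lengths) so that ringing excited by the
# reflection kink has decayed before the retained segment begins.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 30L * (max(length(bf$b), length(bf$a)) - 1L))
  if (pad < 1L) return(signal::filtfilt(bf, x))
  pre <- 2 * x[1] - x[pad + 1L - seq_len(pad) + 1L]
  post <- 2 * x[n] - x[n - seq_len(pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[pad + seq_len(n)]
}

#' Band-pass filter epoched trials
#'
#' Applies the Butterworth band-pass to every channel of every trial,
#' zero-phase (forward-backward), so the motor-imagery window is not shifted
#' by group delay. The squared magnitude response of the forward-backward pass
#' makes the stop-band attenuation twice as steep as the one-pass filter.
#'
#' @param trials an `epoched_trials` object.
#' @param spec a [bandpass_spec()]; `high` must be below `trials$fs / 2`.
#' @return filtered `epoched_trials` of identical shape.
#' @export
bandpass_trials <- function(trials, spec = bandpass_spec()) {
  validate_trials(trials)
  if (spec$high >= trials$fs / 2) {
    stop_invalid("high corner (", spec$high, " Hz) must be below fs/2 = ",
                 trials$fs / 2, " Hz")
  }
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / (trials$fs / 2),
                       type = "pass")
  d <- dim(trials$X)
  out <- trials
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      out$X[i, c, ] <- filtfilt_padded(bf, trials$X[i, c, ])
    }
  }
  out
}

#' Resample epoched trials to a lower sampling rate
#'
#' Zero-phase anti-alias low-pass (8th-order Butterworth at 90% of the target
#' Nyquist) followed by cubic-spline interpolation at the target sample times.
#' The epoch duration is preserved; the output length is
#' `round(T * target_fs / fs)`. Upsampling is not supported.
#'
#' @param trials an `epoched_trials` object.
#' @param target_fs target sampling rate in Hz (`<= trials$fs`).
#' @return resampled `epoched_trials`.
#' @export
resample_trials <- function(trials, target_fs) {
  validate_trials(trials)
  if (!is_number(target_fs) || target_fs <= 0) stop_invalid("target_fs must be > 0")
  if (target_fs > trials$fs) stop_invalid("upsampling is not supported")
  if (target_fs == trials$fs) return(trials)
  d <- dim(trials$X)
  Tout <- round(d[3] * target_fs / trials$fs)
  bf <- signal::butter(8, 0.9 * (target_fs / 2) / (trials$fs / 2), type = "low")
  tt <- (seq_len(d[3]) - 1) / trials$fs
  tn <- (seq_len(Tout) - 1) / target_fs
  X <- array(0, c(d[1], d[2], Tout))
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      xf <- filtfilt_padded(bf, trials$X[i, c, ])
      X[i, c, ] <- spline(tt, xf, xout = tn, method = "natural")$y
    }
  }
  epoched_trials(X, trials$y, target_fs, trials$channel_names,
                 trials$subject_id)
}

#' Select (and reorder) channels by name
#'
#' @param trials an `epoched_trials` object.
#' @param names character vector of channel names; the output carries the
#'   channels in exactly this order. Duplicates are rejected.
#' @return `epoched_trials` with `C = length(names)`.
#' @export
select_channels <- function(trials, names) {
  validate_trials(trials)
  if (anyDuplicated(names)) {
    stop_invalid("duplicate channel names requested: ",
                 paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  idx <- match(names, trials$channel_names)
  if (anyNA(idx)) {
    stop_invalid("unknown channel name(s): ",
                 paste(names[is.na(idx)], collapse = ", "))
  }
  epoched_trials(trials$X[, idx, , drop = FALSE], trials$y, trials$fs,
                 trials$channel_names[idx], trials$subject_id)
}

#' Extract a time window from each trial
#'
#' Sample convention: half-open, 0-based; the window `[start, end)` seconds
#' maps to samples `round(start * fs) .. round(start * fs) + T_out - 1` with
#' `T_out = round((end - start) * fs)`.
#'
#' @param trials an `epoched_trials` object.
#' @param start,end window in seconds, `0 <= start < end <= T/fs`.
#' @return windowed `epoched_trials`.
#' @export
extract_window <- function(trials, start, end) {
  validate_trials(trials)
  d <- dim(trials$X)
  if (!is_number(start) || !is_number(end) || start < 0 || start >= end) {
    stop_invalid("need 0 <= start < end")
  }
  if (end > d[3] / trials$fs + 1e-9) {
    stop_invalid("window end (", end, " s) exceeds trial duration (",
                 d[3] / trials$fs, " s)")
  }
  i0 <- round(start * trials$fs)
  Tout <- round((end - start) * trials$fs)
  if (i0 + Tout > d[3]) Tout <- d[3] - i0
  epoched_trials(trials$X[, , i0 + seq_len(Tout), drop = FALSE], trials$y,
                 trials$fs, trials$channel_names, trials$subject_id)
}

# 20 motor-cortex channels. The published list for the 22-channel montage
# repeats "C1"; the duplicate is replaced by a configurable electrode,
# defaulting to CP2 (the only standard electrode of the printed CP row that
# is absent). This replacement is this package's choice, not a documented
# property of the source montage.
motor20_channels <- function(replacement = "CP2") {
  unique(c("FC3", "FC1", "C1", "FCz", "FC2", "FC4", "C5", "C3", replacement,
           "Cz", "C2", "C4", "C6", "CP3", "CP1", "CPz", "CP4", "P1", "Pz",
           "P2"))
}

#' Dataset preprocessing preset
#'
#' Bundled conventions for the public motor-imagery datasets the method
#' targets: channel subset, target sampling rate and epoch window.
#' `"bciiv2a"` keeps 20 motor-cortex channels and the 3-6 s window at 250 Hz;
#' `"smrbci"` keeps all 15 channels, resampled from 512 to 250 Hz, 0-4 s;
#' `"openbmi"` keeps the same 20-channel motor list at 250 Hz, 0-4 s.
#' Native dataset file importers are out of scope; convert externally to the
#' [save_trials()] layout.
#'
#' @param name one of `"bciiv2a"`, `"smrbci"`, `"openbmi"`, `"custom"`.
#' @param target_fs target sampling rate, Hz.
#' @param window numeric `c(start, end)` in seconds.
#' @param channels character vector of channel names, or `"all"`.
#' @param duplicate_replacement electrode substituted for the duplicated "C1"
#'   in the published 20-channel motor list.
#' @return an object of class `dataset_preset`.
#' @export
dataset_preset <- function(name = c("bciiv2a", "smrbci", "openbmi", "custom"),
                           target_fs = 250, window = NULL, channels = NULL,
                           duplicate_replacement = "CP2") {
  name <- match.arg(name)
  motor <- motor20_channels(duplicate_replacement)
  defaults <- switch(name,
    bciiv2a = list(target_fs = 250, window = c(3, 6), channels = motor),
    smrbci  = list(target_fs = 250, window = c(0, 4), channels = "all"),
    openbmi = list(target_fs = 250, window = c(0, 4), channels = motor),
    custom  = list(target_fs = target_fs, window = window, channels = "all"))
  preset <- structure(
    list(name = name,
         target_fs = if (name == "custom") target_fs else defaults$target_fs,
         window = window %||% defaults$window,
         channels = channels %||% defaults$channels),
    class = "dataset_preset")
  if (is.null(preset$window) || length(preset$window) != 2L ||
      preset$window[1] >= preset$window[2]) {
    stop_invalid("preset window must be c(start, end) with start < end")
  }
  if (!is_number(preset$target_fs) || preset$target_fs <= 0) {
    stop_invalid("target_fs must be > 0")
  }
  preset
}

#' Apply a dataset preset
#'
#' Runs the full preprocessing chain in the fixed order: channel selection,
#' resampling, window extraction, band-pass filtering.
#'
#' @param trials an `epoched_trials` object.
#' @param preset a [dataset_preset()].
#' @param band a [bandpass_spec()].
#' @return preprocessed `epoched_trials`.
#' @export
apply_preset <- function(trials, preset, band = bandpass_spec()) {
  validate_trials(trials)
  out <- trials
  if (!identical(preset$channels, "all")) {
    out <- select_channels(out, preset$channels)
  }
  out <- resample_trials(out, preset$target_fs)
  out <- extract_window(out, preset$window[1], preset$window[2])
  bandpass_trials(out, band)
}
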