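#' Epoched EEG trials
#'
#' The central data container: a tensor of epoched multi-channel EEG trials
#' with integer class labels. Dimensions are trials (N) x channels (C) x
#' samples (T).
#'
#' @param X numeric array of dimension `N x C x T` (signal in volts, arbitrary
#'   scale).
#' @param y integer vector of length N with class labels in `0..M-1`.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length C.
#' @param subject_id integer subject identifier, or `NULL` when unknown.
#' @return an object of class `epoched_trials`.
#' @examples
#' tr <- epoched_trials(array(rnorm(4 * 3 * 100), c(4, 3, 100)),
#'                      y = c(0L, 0L, 1L, 1L), fs = 250)
#' dim(tr$X)
#' @export
epoched_trials <- function(X, y, fs, channel_names = NULL, subject_id = NULL) {
  if (is.null(channel_names)) {
    channel_names <- sprintf("CH%02d", seq_len(dim(X)[2]))
  }
  obj <- structure(
    list(X = X, y = as.integer(y), fs = fs,
         channel_names = as.character(channel_names),
         subject_id = if (is.null(subject_id)) NULL else as.integer(subject_id)),
    class = "epoched_trials")
  validate_trials(obj)
  obj
}

#' Validate an epoched_trials object
#'
#' Checks the structural invariants: label length matches the trial dimension,
#' labels are non-negative integers, `fs > 0`, at least 2 channels and 2
#' samples.
#'
#' @param trials an `epoched_trials` object.
#' @param require_two_classes if `TRUE`, additionally require both of two
#'   classes to be present (needed for model fitting).
#' @return `trials`, invisibly.
#' @export
validate_trials <- function(trials, require_two_classes = FALSE) {
  if (!inherits(trials, "epoched_trials")) {
    stop_invalid("not an epoched_trials object")
  }
  d <- dim(trials$X)
  if (length(d) != 3L) stop_invalid("X must be a 3-d array (trials x channels x samples)")
  if (d[1] != length(trials$y)) {
    stop_invalid("length of y (", length(trials$y),
                 ") does not match the number of trials (", d[1], ")")
  }
  if (!is_number(trials$fs) || trials$fs <= 0) stop_invalid("fs must be > 0")
  if (d[2] < 2L) stop_invalid("at least 2 channels required")
  if (d[3] < 2L) stop_invalid("at least 2 samples per trial required")
  if (length(trials$channel_names) != d[2]) {
    stop_invalid("channel_names length does not match channel count")
  }
  if (anyNA(trials$y) || any(trials$y < 0L)) {
    stop_invalid("labels must be non-negative integers in 0..M-1")
  }
  if (require_two_classes && length(unique(trials$y)) < 2L) {
    stop_invalid("both classes must be present")
  }
  invisible(trials)
}

#' @export
print.epoched_trials <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("epoched_trials: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  classes: %s; subject: %s\n",
              paste(sort(unique(x$y)), collapse = "/"),
              if (is.null(x$subject_id)) "<none>" else x$subject_id))
  invisible(x)
}

n_trials <- function(trials) dim(trials$X)[1]

#' Concatenate several epoched_trials objects
#'
#' Used to pool the training subjects of a leave-one-subject-out fold. All
#' inputs must agree on channels, samples and sampling rate. The pooled object
#' has `subject_id = NULL`.
#'
#' @param trials_list list of `epoched_trials` with identical geometry.
#' @return a single `epoched_trials` object.
#' @export
concat_trials <- function(trials_list) {
  stopifnot(length(trials_list) >= 1L)
  d1 <- dim(trials_list[[1]]$X)
  fs <- trials_list[[1]]$fs
  for (tr in trials_list) {
    d <- dim(tr$X)
    if (!identical(d[2:3], d1[2:3]) || tr$fs != fs) {
      stop_invalid("trials to concatenate have mismatched geometry")
    }
  }
  N <- sum(vapply(trials_list, n_trials, 0L))
  X <- array(0, c(N, d1[2], d1[3]))
  y <- integer(N)
  at <- 0L
  for (tr in trials_list) {
    n <- n_trials(tr)
    X[at + seq_len(n), , ] <- tr$X
    y[at + seq_len(n)] <- tr$y
    at <- at + n
  }
  epoched_trials(X, y, fs, trials_list[[1]]$channel_names, NULL)
}

#' Subset trials by index
#'
#' @param trials an `epoched_trials` object.
#' @param idx trial indices to keep (order preserved).
#' @return the subset as `epoched_trials`.
#' @export
subset_trials <- function(trials, idx) {
  epoched_trials(trials$X[idx, , , drop = FALSE], trials$y[idx], trials$fs,
                 trials$channel_names, trials$subject_id)
}

#' Save epoched trials to the package HDF5 layout
#'
#' The on-disk layout is fixed and bit-exact: datasets `"X"` (N x C x T,
#' 64-bit float), `"y"` (int8), and root attributes `"fs"` (double),
#' `"channel_names"` (string array) and `"subject_id"` (int, -1 encoding
#' `NULL`). The file is written to a temporary sibling and renamed, so an
#' existing file is overwritten atomically.
#'
#' @param trials an `epoched_trials` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_trials <- function(trials, path) {
  validate_trials(trials)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_invalid("directory does not exist: ", dir)
  tmp <- tempfile(pattern = basename(path), tmpdir = dir, fileext = ".tmp")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(tmp)
  d <- dim(trials$X)
  rhdf5::h5createDataset(tmp, "X", dims = d, storage.mode = "double",
                         level = 0)
  rhdf5::h5write(trials$X, tmp, "X")
  rhdf5::h5createDataset(tmp, "y", dims = length(trials$y),
                         H5type = "H5T_STD_I8LE", level = 0)
  rhdf5::h5write(trials$y, tmp, "y")
  fid <- rhdf5::H5Fopen(tmp)
  rhdf5::h5writeAttribute(as.numeric(trials$fs), fid, "fs")
  rhdf5::h5writeAttribute(trials$channel_names, fid, "channel_names")
  rhdf5::h5writeAttribute(as.integer(trials$subject_id %||% -1L), fid,
                          "subject_id")
  rhdf5::H5Fclose(fid)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Load epoched trials from the package HDF5 layout
#'
#' Reads a file written by [save_trials()]. Missing datasets or attributes
#' raise a format error naming the missing key; labels outside `0..M-1` raise
#' a validation error. Trials and channels are never reordered.
#'
#' @param path file path.
#' @return an `epoched_trials` object.
#' @export
load_trials <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (!rhdf5::H5Fis_hdf5(path)) {
    stop_invalid("format error: not an HDF5 file: ", path)
  }
  ls <- rhdf5::h5ls(path)
  have <- ls$name[ls$otype == "H5I_DATASET"]
  for (key in c("X", "y")) {
    if (!key %in% have) stop_invalid("format error: missing dataset \"", key, "\"")
  }
  X <- rhdf5::h5read(path, "X")
  y <- as.integer(rhdf5::h5read(path, "y"))
  fid <- rhdf5::H5Fopen(path)
  attrs <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  for (key in c("fs", "channel_names", "subject_id")) {
    if (!key %in% names(attrs)) {
      stop_invalid("format error: missing attribute \"", key, "\"")
    }
  }
  if (any(y < 0L)) stop_invalid("label values outside 0..M-1")
  M <- max(y) + 1L
  if (!all(y %in% 0:(M - 1L))) stop_invalid("label values outside 0..M-1")
  sid <- as.integer(attrs$subject_id)
  epoched_trials(X, y, as.numeric(attrs$fs),
                 as.character(attrs$channel_names),
                 if (sid < 0L) NULL else sid)
}
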