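`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Derive a child RNG seed from a base seed and two stream indices
#'
#' Deterministic integer mixing so that every (subject, trial) pair owns its
#' own reproducible RNG stream, independent of cohort size or generation
#' order. All arithmetic stays below 2^53 so the hash is exact in doubles.
#'
#' @param seed base integer seed.
#' @param a,b non-negative stream indices (e.g. subject and trial).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, a, b) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% 1000003) * 8191 +
    as.numeric(a) * 131071 + as.numeric(b) * 524287
  h <- (h %% m) * 48271 %% m
  h <- (h * 16807 + 12345) %% m
  as.integer(h)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

deep_copy <- function(params) {
  lapply(params, function(p) {
    q <- p + 0
    dim(q) <- dim(p)
    q
  })
}

zeros_like <- function(params) {
  lapply(params, function(p) {
    q <- numeric(length(p))
    dim(q) <- dim(p)
    q
  })
}
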