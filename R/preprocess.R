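# Preprocessing: temporal difference and block averaging. These are the only
# two operations applied to the raw ECG before the network — no filtering,
# no normalization.

as_samples <- function(signal) {
  if (inherits(signal, "raw_signal")) signal$samples else as.numeric(signal)
}

signal_rate <- function(signal, default = NULL) {
  if (inherits(signal, "raw_signal")) signal$sampling_rate
  else if (!is.null(default)) default
  else stop("sampling rate unknown: pass a raw_signal", call. = FALSE)
}

#' First-order temporal difference of a signal
#'
#' `out[n] = in[n] - in[n-1]` for n >= 1, with `out[0] = 0` by convention so
#' the output keeps the input's length and timebase alignment.
#'
#' @param signal A [raw_signal()] or numeric vector (length >= 2).
#' @param sampling_rate Required when `signal` is a bare vector.
#' @return An object of class `difference_signal` with fields `samples` and
#'   `sampling_rate`.
#' @export
difference_signal <- function(signal, sampling_rate = NULL) {
  x <- as_samples(signal)
  if (length(x) < 2L) stop("difference needs at least 2 samples", call. = FALSE)
  structure(
    list(samples = c(0, diff(x)),
         sampling_rate = signal_rate(signal, sampling_rate)),
    class = "difference_signal"
  )
}

#' Non-overlapping block average (with downsampling)
#'
#' Averages consecutive, non-overlapping blocks of `n_i` samples; the
#' trailing partial block is discarded. The output has
#' `floor(length(x)/n_i)` samples at `sampling_rate / n_i`.
#'
#' @param signal A [raw_signal()] or numeric vector.
#' @param n_i Averaging factor (integer >= 1, at most the signal length).
#' @return Numeric vector of block means.
#' @export
block_average <- function(signal, n_i) {
  x <- as_samples(signal)
  if (!is.numeric(n_i) || length(n_i) != 1L || n_i < 1 || n_i != round(n_i)) {
    stop("`n_i` must be a positive integer", call. = FALSE)
  }
  n_i <- as.integer(n_i)
  if (length(x) < n_i) stop("`n_i` exceeds the signal length", call. = FALSE)
  nb <- length(x) %/% n_i
  .colMeans(x[seq_len(nb * n_i)], n_i, nb)
}

#' Averaged-difference signal (coarse timebase)
#'
#' Block-averages the raw signal by factor `n_i`, then applies the
#' first-order difference with the same `out[0] = 0` convention. This is the
#' input of the object-level (coarse) network branch.
#'
#' The default `n_i = 5` is fixed by the window geometry: a 56-sample window
#' must span 0.78 s on this timebase and 0.16 s on the raw-difference
#' timebase at 360 Hz, which forces an averaging factor of 5.
#'
#' @inheritParams block_average
#' @param sampling_rate Required when `signal` is a bare vector.
#' @return An object of class `avg_difference_signal` with fields `samples`,
#'   `effective_rate` (Hz) and `n_i`.
#' @export
average_difference <- function(signal, n_i = 5L, sampling_rate = NULL) {
  avg <- block_average(signal, n_i)
  if (length(avg) < 2L) stop("signal too short for averaged difference", call. = FALSE)
  fs <- signal_rate(signal, sampling_rate)
  structure(
    list(samples = c(0, diff(avg)),
         effective_rate = fs / n_i,
         n_i = as.integer(n_i)),
    class = "avg_difference_signal"
  )
}
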