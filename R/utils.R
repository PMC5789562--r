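# Shared internal helpers: seeding, rounding, validation.

#' Round half away from zero
#'
#' Detection tables are conventionally printed with half-up rounding
#' (base `round()` is round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible sub-stream seed (< 2^31) from a master seed, so e.g.
# the noise stream can vary while the beat schedule stays fixed.
sub_seed <- function(seed, k) {
  ((as.numeric(seed) %% 2147483647) * 48271 + 9973 * as.numeric(k)) %% 2147483647
}

# Evaluate fn() under a given RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, fn) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = ge)
    } else if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
      rm(".Random.seed", envir = ge)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  fn()
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

#' Construct a raw single-lead ECG signal
#'
#' @param samples Numeric vector of amplitudes in mV, one per sample.
#' @param sampling_rate Sampling rate in Hz.
#' @param record_id Optional identifier carried through the pipeline.
#' @return An object of class `raw_signal` with fields `samples`,
#'   `sampling_rate`, `record_id`.
#' @export
raw_signal <- function(samples, sampling_rate, record_id = "record") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples))) stop("signal contains non-finite samples (NaN/Inf)", call. = FALSE)
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         record_id = as.character(record_id)[1]),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %s: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Construct a set of beat annotations
#'
#' R-peak fiducials (and optionally per-beat Q and S landmarks) as 0-based
#' sample indices on the raw timebase.
#'
#' @param r_indices Strictly increasing 0-based R-peak sample indices.
#' @param q_indices,s_indices Optional per-beat Q/S landmark indices.
#' @param n_samples Optional record length for bounds checking.
#' @param sampling_rate Optional; when given, consecutive R indices must be
#'   at least 0.2 s apart (the physiological refractory bound).
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(r_indices, q_indices = NULL, s_indices = NULL,
                             n_samples = NULL, sampling_rate = NULL) {
  r <- as.numeric(r_indices)
  if (any(!is.finite(r)) || any(r < 0)) stop("annotation indices must be nonnegative", call. = FALSE)
  if (length(r) > 1L && any(diff(r) <= 0)) stop("R indices must be strictly increasing", call. = FALSE)
  if (!is.null(n_samples) && length(r) && max(r) >= n_samples) {
    stop("annotation index beyond record length", call. = FALSE)
  }
  if (!is.null(sampling_rate) && length(r) > 1L && any(diff(r) < 0.2 * sampling_rate)) {
    stop("consecutive R indices closer than 0.2 s", call. = FALSE)
  }
  structure(
    list(r_indices = r,
         q_indices = if (!is.null(q_indices)) as.numeric(q_indices),
         s_indices = if (!is.null(s_indices)) as.numeric(s_indices)),
    class = "beat_annotations"
  )
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beats%s\n", length(x$r_indices),
              if (!is.null(x$q_indices)) " (+Q/S landmarks)" else ""))
  invisible(x)
}

#' Bundle a signal with its annotations
#'
#' @param signal A [raw_signal()].
#' @param annotations A [beat_annotations()] or `NULL`.
#' @param source_format Provenance tag, e.g. `"csv"` or `"synthetic"`.
#' @return An object of class `record_bundle`.
#' @export
record_bundle <- function(signal, annotations = NULL, source_format = "synthetic") {
  stopifnot(inherits(signal, "raw_signal"))
  if (!is.null(annotations)) {
    stopifnot(inherits(annotations, "beat_annotations"))
    if (length(annotations$r_indices) &&
        max(annotations$r_indices) >= length(signal$samples)) {
      stop("annotation index beyond signal length", call. = FALSE)
    }
  }
  structure(list(signal = signal, annotations = annotations,
                 source_format = source_format),
            class = "record_bundle")
}
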