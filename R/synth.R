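# Synthetic single-lead ECG generation.
#
# Each beat is a superposition of five Gaussian deflections (P, Q, R, S, T)
# centered at RR-scheduled R times plus per-wave offsets, over optional
# sinusoidal baseline wander. The generator emits ground-truth R (and Q/S)
# sample indices so every downstream stage can be scored without external
# databases.

default_wave_params <- function() {
  data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.15, 1.0, -0.2, 0.3),   # mV
    width     = c(0.045, 0.015, 0.02, 0.015, 0.07), # Gaussian sd, s
    offset    = c(-0.2, -0.04, 0.0, 0.04, 0.3),   # s relative to R
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic ECG generator
#'
#' @param sampling_rate Sampling rate in Hz (default 360, the rate of the
#'   MIT-BIH arrhythmia recordings this generator stands in for).
#' @param duration Record duration in seconds.
#' @param mean_hr Mean heart rate, beats/min (20–300).
#' @param hr_jitter Fractional standard deviation of the RR interval
#'   (lognormal multiplicative jitter).
#' @param wave_params Data frame with columns `wave`, `amplitude` (mV),
#'   `width` (Gaussian sd, s) and `offset` (s from the R apex) for the five
#'   waves P, Q, R, S, T.
#' @param baseline_wander_amplitude Amplitude of sinusoidal baseline wander
#'   in mV (0 disables).
#' @param baseline_wander_freq Baseline wander frequency in Hz.
#' @param amp_jitter Fractional per-beat amplitude jitter (applied to all
#'   waves of a beat jointly, so relative wave amplitudes are preserved).
#' @param seed Default seed used when [generate_record()] is called without
#'   one.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 360, duration = 60, mean_hr = 72,
                         hr_jitter = 0.05, wave_params = default_wave_params(),
                         baseline_wander_amplitude = 0.05,
                         baseline_wander_freq = 0.33,
                         amp_jitter = 0.05, seed = 1L) {
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  stop_if_not_scalar_pos(duration, "duration")
  if (!is.numeric(mean_hr) || mean_hr < 20 || mean_hr > 300) {
    stop("`mean_hr` must lie in [20, 300] beats/min", call. = FALSE)
  }
  if (hr_jitter < 0 || amp_jitter < 0 || baseline_wander_amplitude < 0) {
    stop("jitter and wander amplitudes must be nonnegative", call. = FALSE)
  }
  wp <- wave_params
  need <- c("wave", "amplitude", "width", "offset")
  if (!all(need %in% names(wp)) || !setequal(wp$wave, c("P", "Q", "R", "S", "T"))) {
    stop("`wave_params` must describe exactly the waves P, Q, R, S, T", call. = FALSE)
  }
  wp <- wp[match(c("P", "Q", "R", "S", "T"), wp$wave), ]
  if (any(wp$width <= 0)) stop("wave widths must be positive", call. = FALSE)
  ar <- abs(wp$amplitude[wp$wave == "R"])
  if (ar <= abs(wp$amplitude[wp$wave == "P"]) || ar <= abs(wp$amplitude[wp$wave == "T"])) {
    stop("R amplitude must exceed P and T amplitudes in magnitude", call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate, duration = duration, mean_hr = mean_hr,
         hr_jitter = hr_jitter, wave_params = wp,
         baseline_wander_amplitude = baseline_wander_amplitude,
         baseline_wander_freq = baseline_wander_freq,
         amp_jitter = amp_jitter, seed = seed),
    class = "synth_config"
  )
}

#' Generate an annotated synthetic ECG record
#'
#' RR intervals are drawn as `60/mean_hr` times lognormal multiplicative
#' jitter (sdlog = `hr_jitter`, mean-corrected), clipped to the
#' physiological range \[0.3 s, 2.0 s\]. The master seed is split into
#' independent sub-streams (schedule, per-beat morphology, wander phase), so
#' later noise injection can vary its own seed while the beats stay fixed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; defaults to `config$seed`. Output is a pure
#'   function of `(config, seed)`.
#' @param record_id Identifier for the generated record.
#' @return A [record_bundle()] whose annotations carry ground-truth R, Q and
#'   S sample indices (0-based).
#' @export
generate_record <- function(config, seed = config$seed, record_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  dur <- config$duration
  base_rr <- 60 / config$mean_hr
  margin <- 0.15 # keep full QRS support inside the record

  t0 <- 0.5 * base_rr
  n_draw <- ceiling((dur - t0) / 0.3) + 2L
  rr <- with_seed_(sub_seed(seed, 1L), function() {
    r <- base_rr * exp(rnorm(n_draw, mean = -config$hr_jitter^2 / 2,
                             sd = config$hr_jitter))
    pmin(pmax(r, 0.3), 2.0)
  })
  r_times <- t0 + cumsum(c(0, rr))
  r_times <- r_times[r_times >= margin & r_times <= dur - margin]
  if (length(r_times) < 1L) {
    stop("duration too short to fit a single beat", call. = FALSE)
  }
  nb <- length(r_times)

  beat_scale <- if (config$amp_jitter > 0) {
    with_seed_(sub_seed(seed, 2L), function() {
      exp(rnorm(nb, mean = -config$amp_jitter^2 / 2, sd = config$amp_jitter))
    })
  } else rep(1, nb)

  phase <- if (config$baseline_wander_amplitude > 0) {
    with_seed_(sub_seed(seed, 3L), function() runif(1, 0, 2 * pi))
  } else 0

  n <- round(dur * fs)
  tt <- (0:(n - 1L)) / fs
  x <- numeric(n)
  wp <- config$wave_params
  for (b in seq_len(nb)) {
    for (w in seq_len(nrow(wp))) {
      c0 <- r_times[b] + wp$offset[w]
      sdw <- wp$width[w]
      a <- wp$amplitude[w] * beat_scale[b]
      i0 <- max(1L, floor((c0 - 4 * sdw) * fs) + 1L)
      i1 <- min(n, ceiling((c0 + 4 * sdw) * fs) + 1L)
      if (i0 <= i1) {
        idx <- i0:i1
        x[idx] <- x[idx] + a * exp(-((tt[idx] - c0)^2) / (2 * sdw^2))
      }
    }
  }
  if (config$baseline_wander_amplitude > 0) {
    x <- x + config$baseline_wander_amplitude *
      sin(2 * pi * config$baseline_wander_freq * tt + phase)
  }

  to_idx <- function(times) pmin(pmax(round(times * fs), 0), n - 1L)
  off <- stats::setNames(wp$offset, wp$wave)
  ann <- beat_annotations(
    r_indices = to_idx(r_times),
    q_indices = to_idx(r_times + off[["Q"]]),
    s_indices = to_idx(r_times + off[["S"]]),
    n_samples = n
  )
  record_bundle(raw_signal(x, fs, record_id), ann, source_format = "synthetic")
}

#' Add white Gaussian noise at a requested SNR
#'
#' Noise variance is `P_signal / 10^(snr_db/10)` where `P_signal` is the
#' mean square of the mean-removed input (whole-record power reference).
#' `snr_db = Inf` disables noise and returns the input unchanged.
#'
#' @param signal A [raw_signal()].
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed for the noise stream.
#' @return A [raw_signal()] of the same length.
#' @export
add_gaussian_noise <- function(signal, snr_db, seed = 1L) {
  stopifnot(inherits(signal, "raw_signal"))
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    stop("`snr_db` must be a single number (Inf disables noise)", call. = FALSE)
  }
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  if (!is.finite(snr_db)) stop("`snr_db` must be finite or +Inf", call. = FALSE)
  x <- signal$samples
  p <- mean((x - mean(x))^2)
  if (p == 0) stop("constant (zero-power) signal: SNR undefined", call. = FALSE)
  sigma <- sqrt(p / 10^(snr_db / 10))
  noise <- with_seed_(seed, function() rnorm(length(x), 0, sigma))
  raw_signal(x + noise, signal$sampling_rate, signal$record_id)
}

#' Build a balanced labeled training corpus from synthetic ECG
#'
#' Generates a record with at least `n_qrs` beats and draws a balanced
#' dataset of `n_qrs` segment pairs per class (Q, R, S, non-QRS) via
#' [build_dataset()].
#'
#' @param config A [synth_config()], or `NULL` to auto-size a default
#'   configuration whose duration accommodates `n_qrs` beats.
#' @param n_qrs Number of QRS complexes (per-class pair count), >= 4.
#' @param seed Integer seed controlling both the record and the sampling.
#' @param n_i Averaging factor of the coarse timebase (see
#'   [average_difference()]).
#' @return A `segment_dataset` (see [build_dataset()]); the source record is
#'   attached as attribute `"record"`.
#' @export
make_training_corpus <- function(config = NULL, n_qrs = 400, seed = 1L, n_i = 5L) {
  if (n_qrs < 4) stop("`n_qrs` must be at least 4", call. = FALSE)
  if (is.null(config)) {
    # a dozen spare beats: edge beats are unscannable and the RR schedule
    # jitters, so size the record with headroom for every class
    config <- synth_config(duration = ceiling((n_qrs + 12) * 60 / 72))
  }
  rec <- generate_record(config, seed = sub_seed(seed, 11L), record_id = "corpus")
  if (length(rec$annotations$r_indices) < n_qrs) {
    stop(sprintf("record too short: %d beats generated but %d QRS complexes requested",
                 length(rec$annotations$r_indices), n_qrs), call. = FALSE)
  }
  ds <- build_dataset(rec, n_i = n_i,
                      balance = c(Q = n_qrs, R = n_qrs, S = n_qrs, NONQRS = n_qrs),
                      seed = sub_seed(seed, 12L))
  attr(ds, "record") <- rec
  ds
}
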