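# Beat-detection scoring: one-to-one matching of predicted against
# reference R-peaks within a tolerance window, the four standard metrics
#   Sen = TP/(TP+FN)   PPR = TP/(TP+FP)
#   DER = (FN+FP)/(TP+FN)   Acc = TP/(TP+FP+FN)   (all in %)
# and SNR degradation sweeps.

ann_indices <- function(x) {
  if (inherits(x, "beat_annotations") || inherits(x, "detection_result")) x$r_indices
  else as.numeric(x)
}

#' Match predicted to reference beats
#'
#' Greedy one-to-one nearest-neighbor matching: candidate (prediction,
#' reference) pairs within `tol_s` are assigned in order of increasing
#' distance (leftmost wins ties); each beat is used at most once. When
#' beats are separated by more than twice the tolerance — always true under
#' a 0.2 s refractory and the default 0.15 s tolerance — this equals the
#' optimal assignment.
#'
#' @param pred,ref Predicted / reference beats: `detection_result`,
#'   [beat_annotations()] or bare 0-based index vectors (sorted).
#' @param tol_s Match tolerance in seconds (default 0.15 s, the standard
#'   beat-matching window).
#' @param sampling_rate Sampling rate, Hz.
#' @return An object of class `eval_counts` with integer fields `tp`,
#'   `fp`, `fn`; always `tp + fn = |ref|` and `tp + fp = |pred|`.
#' @export
match_beats <- function(pred, ref, tol_s = 0.15, sampling_rate = 360) {
  p <- ann_indices(pred)
  r <- ann_indices(ref)
  tol <- tol_s * sampling_rate
  if (!length(p) || !length(r)) {
    return(structure(list(tp = 0L, fp = length(p), fn = length(r)),
                     class = "eval_counts"))
  }
  di <- pi <- ri <- numeric(0)
  for (i in seq_along(p)) {
    lo <- findInterval(p[i] - tol, r, left.open = TRUE) + 1L
    hi <- findInterval(p[i] + tol, r)
    if (lo <= hi) {
      js <- lo:hi
      di <- c(di, abs(p[i] - r[js]))
      pi <- c(pi, rep(i, length(js)))
      ri <- c(ri, js)
    }
  }
  tp <- 0L
  if (length(di)) {
    used_p <- logical(length(p))
    used_r <- logical(length(r))
    for (k in order(di, pi, ri)) {
      if (!used_p[pi[k]] && !used_r[ri[k]]) {
        used_p[pi[k]] <- TRUE
        used_r[ri[k]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  structure(list(tp = tp, fp = length(p) - tp, fn = length(r) - tp),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts> TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Detection metrics from TP/FP/FN counts
#'
#' Full precision is retained internally; use [round_metrics()] (or the
#' print method) for the conventional 2-decimal report.
#'
#' @param counts An `eval_counts` (or list with `tp`, `fp`, `fn`).
#' @param strict If `TRUE` (default), a zero denominator (`tp + fn == 0` or
#'   `tp + fp == 0`) is an error; if `FALSE` the undefined metric is `NA`
#'   (and Sen/Acc are 0 when no reference beat is matched).
#' @return An object of class `qrs_metrics` with percentage fields `sen`,
#'   `ppr`, `der`, `acc` and the counts.
#' @export
detection_metrics <- function(counts, strict = TRUE) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (strict && (tp + fn == 0 || tp + fp == 0)) {
    stop("undefined metric: zero denominator (no reference or no predicted beats)",
         call. = FALSE)
  }
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppr <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  der <- if (tp + fn > 0) 100 * (fn + fp) / (tp + fn) else NA_real_
  acc <- if (tp + fp + fn > 0) 100 * tp / (tp + fp + fn) else NA_real_
  structure(list(sen = sen, ppr = ppr, der = der, acc = acc,
                 tp = tp, fp = fp, fn = fn),
            class = "qrs_metrics")
}

#' Round metrics to the conventional 2-decimal report (half away from zero)
#'
#' @param m A `qrs_metrics`.
#' @param digits Decimal places.
#' @return Named numeric vector (sen, ppr, der, acc).
#' @export
round_metrics <- function(m, digits = 2) {
  c(sen = round_half_up(m$sen, digits), ppr = round_half_up(m$ppr, digits),
    der = round_half_up(m$der, digits), acc = round_half_up(m$acc, digits))
}

#' @export
print.qrs_metrics <- function(x, ...) {
  r <- round_metrics(x)
  cat(sprintf("<qrs_metrics> Sen %.2f%%  PPR %.2f%%  DER %.2f%%  Acc %.2f%%  (TP=%d FP=%d FN=%d)\n",
              r["sen"], r["ppr"], r["der"], r["acc"], x$tp, x$fp, x$fn))
  invisible(x)
}

metrics_row <- function(record_id, total, m) {
  data.frame(record = record_id, total_beats = total,
             tp = m$tp, fp = m$fp, fn = m$fn,
             sen = m$sen, ppr = m$ppr, der = m$der, acc = m$acc,
             stringsAsFactors = FALSE)
}

#' Evaluate a trained model on one annotated record
#'
#' Runs [detect_beats()], matches against the reference annotations and
#' computes the metrics.
#'
#' @param record An annotated [record_bundle()].
#' @param model A trained [train_qrsnet()] model.
#' @param tol_s Match tolerance, s.
#' @param ... Passed to [detect_beats()].
#' @return One-row data frame: record, total_beats, tp, fp, fn, sen, ppr,
#'   der, acc (full precision; round at report time).
#' @export
evaluate_record <- function(record, model, tol_s = 0.15, ...) {
  stopifnot(inherits(record, "record_bundle"))
  if (is.null(record$annotations)) stop("record has no annotations", call. = FALSE)
  det <- detect_beats(record, model, ...)
  cts <- match_beats(det, record$annotations, tol_s = tol_s,
                     sampling_rate = record$signal$sampling_rate)
  m <- detection_metrics(cts, strict = FALSE)
  metrics_row(record$signal$record_id, length(record$annotations$r_indices), m)
}

#' Evaluate several records with a pooled summary row
#'
#' Per-record rows plus an `"overall"` row whose metrics are computed from
#' the summed TP/FP/FN counts (not averaged percentages).
#'
#' @param records List of annotated [record_bundle()]s.
#' @inheritParams evaluate_record
#' @return Data frame, one row per record plus the pooled row.
#' @export
evaluate_records <- function(records, model, tol_s = 0.15, ...) {
  rows <- do.call(rbind, lapply(records, evaluate_record, model = model,
                                tol_s = tol_s, ...))
  pooled <- detection_metrics(list(tp = sum(rows$tp), fp = sum(rows$fp),
                                   fn = sum(rows$fn)), strict = FALSE)
  rbind(rows, metrics_row("overall", sum(rows$total_beats), pooled))
}

#' SNR degradation sweep
#'
#' Evaluates the model on noise-corrupted copies of the record(s) at each
#' requested SNR, averaged over `n_seeds` noise realizations, plus a
#' noise-free baseline row (`snr_db = Inf`). The same seed list is reused
#' at every SNR level (paired design), so the degradation trend is not
#' confounded by seed-to-seed variation.
#'
#' @param records One annotated [record_bundle()] or a list of them (counts
#'   are pooled across records within each seed).
#' @param model A trained model.
#' @param snr_db SNR levels in dB, high to low.
#' @param n_seeds Noise realizations per SNR.
#' @param tol_s Match tolerance, s.
#' @param base_seed Master seed for the noise sub-streams.
#' @param ... Passed to [detect_beats()].
#' @return Data frame with `length(snr_db) + 1` rows: snr_db, sen, ppr,
#'   der, acc (per-SNR means over seeds, from seed-pooled counts).
#' @export
snr_sweep <- function(records, model, snr_db = c(90, 80, 70, 60, 50, 40, 30, 20, 10),
                      n_seeds = 5L, tol_s = 0.15, base_seed = 1L, ...) {
  if (inherits(records, "record_bundle")) records <- list(records)
  eval_noisy <- function(snr, seed) {
    cts <- lapply(records, function(rec) {
      sig <- if (is.finite(snr)) add_gaussian_noise(rec$signal, snr, seed = seed)
             else rec$signal
      det <- detect_beats(sig, model, ...)
      match_beats(det, rec$annotations, tol_s = tol_s,
                  sampling_rate = sig$sampling_rate)
    })
    detection_metrics(list(tp = sum(vapply(cts, `[[`, 0L, "tp")),
                           fp = sum(vapply(cts, `[[`, 0L, "fp")),
                           fn = sum(vapply(cts, `[[`, 0L, "fn"))),
                      strict = FALSE)
  }
  seeds <- vapply(seq_len(n_seeds), function(s) sub_seed(base_seed, s), 0)
  rows <- lapply(c(Inf, snr_db), function(snr) {
    ms <- if (is.finite(snr)) lapply(seeds, function(s) eval_noisy(snr, s))
          else list(eval_noisy(snr, seeds[1]))
    data.frame(snr_db = snr,
               sen = mean(vapply(ms, `[[`, 0, "sen")),
               ppr = mean(vapply(ms, `[[`, 0, "ppr")),
               der = mean(vapply(ms, `[[`, 0, "der")),
               acc = mean(vapply(ms, `[[`, 0, "acc")))
  })
  do.call(rbind, rows)
}
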