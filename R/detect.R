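# Sliding detection: run the trained classifier at every valid detection
# center (stride = one averaged sample), then turn the R-posterior stream
# into discrete beat locations with thresholding, refractory suppression
# and raw-signal peak refinement.

#' Scan a record with a trained model
#'
#' Preprocesses the record, extracts the aligned segment pair at every valid
#' averaged-timebase center, and evaluates the network. Deterministic.
#'
#' @param signal A [raw_signal()].
#' @param model A [train_qrsnet()] model.
#' @param chunk Centers per forward batch (memory control).
#' @return An object of class `posterior_stream`: 0-based `centers_avg` /
#'   `centers_raw`, an `n x 4` posterior matrix (columns Q, R, S, NONQRS,
#'   each row summing to 1), `effective_rate`, `n_i`, `sampling_rate`.
#' @export
scan_record <- function(signal, model, chunk = 4096L) {
  stopifnot(inherits(signal, "raw_signal"), inherits(model, "qrs_model"))
  n_i <- model$n_i
  centers <- valid_centers(length(signal$samples), n_i)
  if (!length(centers)) stop("record too short to scan", call. = FALSE)
  sd <- difference_signal(signal)$samples
  sad <- average_difference(signal, n_i)$samples
  post <- matrix(0, length(centers), 4L, dimnames = list(NULL, CLASS_LEVELS))
  for (s in seq.int(1L, length(centers), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(centers))
    w <- extract_windows(sd, sad, centers[idx], n_i)
    post[idx, ] <- forward_batch(model$params, model$spec, w$object, w$part)
  }
  structure(
    list(centers_avg = centers,
         centers_raw = center_raw_index(centers, n_i),
         posterior = post,
         effective_rate = signal$sampling_rate / n_i,
         n_i = n_i, sampling_rate = signal$sampling_rate),
    class = "posterior_stream"
  )
}

# Greedy non-maximum suppression: keep detections in decreasing confidence
# order (earlier index wins ties), drop any within `refr` samples of a kept
# one. Inputs need not be sorted; output is sorted by index.
suppress_refractory <- function(idx, conf, refr) {
  if (!length(idx)) return(list(idx = numeric(0), conf = numeric(0)))
  ord <- order(-conf, idx)
  keep_idx <- numeric(0)
  keep_conf <- numeric(0)
  for (j in ord) {
    if (!length(keep_idx) || all(abs(keep_idx - idx[j]) >= refr)) {
      keep_idx <- c(keep_idx, idx[j])
      keep_conf <- c(keep_conf, conf[j])
    }
  }
  o <- order(keep_idx)
  list(idx = keep_idx[o], conf = keep_conf[o])
}

#' Convert a posterior stream into discrete beat detections
#'
#' Contiguous runs where the R posterior exceeds `threshold` become
#' candidate events located at the run's maximal-posterior center (mapped
#' to the raw timebase); events closer than the refractory period keep only
#' the higher-confidence one.
#'
#' @param stream A [scan_record()] posterior stream.
#' @param threshold Event threshold on the R posterior.
#' @param refractory_s Minimum admissible spacing between detections, s.
#' @return An object of class `detection_result`: 0-based `r_indices` (raw
#'   timebase, strictly increasing), per-beat `confidence`,
#'   `sampling_rate`. An empty result is valid.
#' @export
decide_detections <- function(stream, threshold = 0.5, refractory_s = 0.2) {
  stopifnot(inherits(stream, "posterior_stream"))
  r <- stream$posterior[, "R"]
  above <- r > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- conf <- numeric(0)
  for (k in which(runs$values)) {
    span <- starts[k]:ends[k]
    best <- span[which.max(r[span])]
    idx <- c(idx, stream$centers_raw[best])
    conf <- c(conf, r[best])
  }
  kept <- suppress_refractory(idx, conf, refractory_s * stream$sampling_rate)
  structure(
    list(r_indices = kept$idx, confidence = kept$conf,
         sampling_rate = stream$sampling_rate,
         threshold = threshold, refractory_s = refractory_s),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d beats (threshold %.2f, refractory %.2f s)\n",
              length(x$r_indices), x$threshold, x$refractory_s))
  invisible(x)
}

#' Refine detections to the local raw-signal apex
#'
#' Moves each detection to the maximal-|amplitude| sample of the raw signal
#' within `window_s`, but only on strict improvement (ties, e.g. on a flat
#' signal, keep the current index; among strictly better samples the
#' leftmost wins). The refractory constraint is re-asserted afterwards.
#'
#' @param detections A [decide_detections()] result.
#' @param signal The [raw_signal()] that was scanned.
#' @param window_s Refinement half-window, s.
#' @return A refined `detection_result`.
#' @export
refine_to_peak <- function(detections, signal, window_s = 0.05) {
  stopifnot(inherits(detections, "detection_result"), inherits(signal, "raw_signal"))
  x <- abs(signal$samples)
  n <- length(x)
  w <- round(window_s * signal$sampling_rate)
  idx <- detections$r_indices
  for (j in seq_along(idx)) {
    lo <- max(0, idx[j] - w)
    hi <- min(n - 1, idx[j] + w)
    seg <- x[(lo + 1):(hi + 1)]
    best <- lo + which.max(seg) - 1
    if (x[best + 1] > x[idx[j] + 1]) idx[j] <- best
  }
  kept <- suppress_refractory(idx, detections$confidence,
                              detections$refractory_s * signal$sampling_rate)
  structure(
    list(r_indices = kept$idx, confidence = kept$conf,
         sampling_rate = detections$sampling_rate,
         threshold = detections$threshold,
         refractory_s = detections$refractory_s),
    class = "detection_result"
  )
}

#' Detect beats in a record (scan + decide + refine)
#'
#' @param signal A [raw_signal()] or [record_bundle()].
#' @param model A trained [train_qrsnet()] model.
#' @param threshold R-posterior event threshold.
#' @param refractory_s Refractory period, s.
#' @param refine_window_s Peak-refinement half-window, s (`NULL` or 0 to
#'   skip refinement).
#' @return A `detection_result`.
#' @export
detect_beats <- function(signal, model, threshold = 0.5, refractory_s = 0.2,
                         refine_window_s = 0.05) {
  if (inherits(signal, "record_bundle")) signal <- signal$signal
  stream <- scan_record(signal, model)
  det <- decide_detections(stream, threshold = threshold,
                           refractory_s = refractory_s)
  if (!is.null(refine_window_s) && refine_window_s > 0) {
    det <- refine_to_peak(det, signal, refine_window_s)
  }
  det
}
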