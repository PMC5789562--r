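# Dual-timebase segmentation: 56-sample windows (22 samples before the
# detection point, 33 after) cut from the difference signal (fine, part
# level) and the averaged-difference signal (coarse, object level), aligned
# at a common detection point.

SEG_BEFORE <- 22L
SEG_AFTER <- 33L
SEG_LEN <- SEG_BEFORE + 1L + SEG_AFTER # 56

#' Time spanned by one 56-sample window on each timebase
#'
#' @param sampling_rate Raw sampling rate in Hz.
#' @param n_i Averaging factor of the coarse timebase.
#' @return Named vector with the window span in seconds on the `part`
#'   (difference) and `object` (averaged-difference) timebases. At 360 Hz
#'   with `n_i = 5` these are 0.16 s and 0.78 s.
#' @export
window_span_s <- function(sampling_rate = 360, n_i = 5L) {
  c(part = SEG_LEN / sampling_rate,
    object = SEG_LEN / (sampling_rate / n_i))
}

# Raw-timebase index of an averaged-timebase center (0-based both sides):
# the center of averaging block c.
center_raw_index <- function(center_avg, n_i) {
  center_avg * n_i + n_i %/% 2L
}

# All averaged-timebase centers whose object AND part windows fit inside a
# record of `len_raw` samples. 0-based.
valid_centers <- function(len_raw, n_i) {
  len_avg <- len_raw %/% n_i
  hi <- min(len_avg - 1L - SEG_AFTER,
            (len_raw - 1L - SEG_AFTER - n_i %/% 2L) %/% n_i)
  if (hi < SEG_BEFORE) return(integer(0))
  SEG_BEFORE:hi
}

# Batched window extraction. sd/sad are bare sample vectors; centers are
# 0-based averaged-timebase indices (assumed valid). Returns 56-column
# matrices, one row per center.
extract_windows <- function(sd_samples, sad_samples, centers_avg, n_i) {
  offs <- (-SEG_BEFORE):SEG_AFTER
  cr <- center_raw_index(centers_avg, n_i)
  obj <- matrix(sad_samples[outer(centers_avg, offs, "+") + 1L],
                nrow = length(centers_avg))
  part <- matrix(sd_samples[outer(cr, offs, "+") + 1L],
                 nrow = length(centers_avg))
  list(object = obj, part = part, centers_avg = centers_avg, centers_raw = cr)
}

#' Extract one aligned segment pair
#'
#' Cuts the 56-sample object-level window from the averaged-difference
#' signal around `center_avg_index` and the 56-sample part-level window from
#' the difference signal around the corresponding raw index
#' `center_avg_index * n_i + floor(n_i/2)`. Both windows cover
#' `[center - 22, center + 33]` on their own timebase.
#'
#' @param sd A [difference_signal()].
#' @param sad An [average_difference()] signal.
#' @param center_avg_index 0-based index on the averaged timebase.
#' @return An object of class `segment_pair` with fields `part_window`,
#'   `object_window` (length 56 each), `center_avg_index`,
#'   `center_raw_index`.
#' @export
extract_pair <- function(sd, sad, center_avg_index) {
  stopifnot(inherits(sd, "difference_signal"), inherits(sad, "avg_difference_signal"))
  n_i <- sad$n_i
  c0 <- as.integer(center_avg_index)
  cr <- center_raw_index(c0, n_i)
  if (c0 - SEG_BEFORE < 0L || c0 + SEG_AFTER > length(sad$samples) - 1L ||
      cr - SEG_BEFORE < 0L || cr + SEG_AFTER > length(sd$samples) - 1L) {
    stop("segment window out of bounds at center ", c0, call. = FALSE)
  }
  w <- extract_windows(sd$samples, sad$samples, c0, n_i)
  structure(
    list(part_window = as.numeric(w$part[1L, ]),
         object_window = as.numeric(w$object[1L, ]),
         center_avg_index = c0, center_raw_index = cr),
    class = "segment_pair"
  )
}

CLASS_LEVELS <- c("Q", "R", "S", "NONQRS")

#' One-hot target vector for a class label
#'
#' @param label Character vector of labels in `Q, R, S, NONQRS`.
#' @return Matrix with one row per label and columns Q, R, S, NONQRS;
#'   exactly one 1 per row.
#' @export
one_hot <- function(label) {
  f <- factor(as.character(label), levels = CLASS_LEVELS)
  if (anyNA(f)) stop("unknown class label", call. = FALSE)
  m <- matrix(0, length(f), length(CLASS_LEVELS),
              dimnames = list(NULL, CLASS_LEVELS))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# Distance from each x to the nearest element of sorted ref.
nearest_dist <- function(x, ref) {
  if (is.null(ref) || !length(ref)) return(rep(Inf, length(x)))
  i <- findInterval(x, ref)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(ref))
  pmin(abs(x - ref[lo]), abs(x - ref[hi]))
}

#' Label a detection point against reference annotations
#'
#' A center is labeled `R` if its raw index lies within `tol_r` raw samples
#' of an annotated R (default: one averaged sample, i.e. `n_i` raw samples);
#' `Q`/`S` if within `tol_qs` raw samples of the beat's Q/S landmark;
#' `NONQRS` if farther than `nonqrs_radius_s` from every R. Centers in the
#' ambiguous band between the QRS zone and the non-QRS zone get `NA` and are
#' excluded from training.
#'
#' @param center_raw_index Vector of 0-based raw-timebase indices.
#' @param annotations A [beat_annotations()] (with Q/S landmarks for Q/S
#'   labeling; see [locate_qs()]).
#' @param sampling_rate Raw sampling rate, Hz.
#' @param n_i Averaging factor (sets the default R tolerance).
#' @param tol_r,tol_qs Tolerances in raw samples.
#' @param nonqrs_radius_s Exclusion radius around each R for `NONQRS`, s.
#' @return Character vector over `Q, R, S, NONQRS`, `NA` = excluded.
#' @export
label_center <- function(center_raw_index, annotations, sampling_rate,
                         n_i = 5L, tol_r = n_i, tol_qs = 2L,
                         nonqrs_radius_s = 0.2) {
  stopifnot(inherits(annotations, "beat_annotations"))
  cr <- as.numeric(center_raw_index)
  dr <- nearest_dist(cr, annotations$r_indices)
  dq <- nearest_dist(cr, annotations$q_indices)
  ds <- nearest_dist(cr, annotations$s_indices)
  lab <- rep(NA_character_, length(cr))
  lab[dr > nonqrs_radius_s * sampling_rate] <- "NONQRS"
  lab[ds <= tol_qs] <- "S"
  lab[dq <= tol_qs] <- "Q"
  lab[dr <= tol_r] <- "R"
  lab
}

#' Derive Q and S landmarks from the raw signal
#'
#' Beat annotations often mark only the R fiducial. The Q (S) landmark of
#' each beat is located as the minimum of the raw signal within `search_s`
#' seconds before (after) the annotated R.
#'
#' @param signal A [raw_signal()].
#' @param r_indices 0-based R sample indices.
#' @param search_s Search half-window in seconds.
#' @return List with numeric vectors `q` and `s` (0-based indices).
#' @export
locate_qs <- function(signal, r_indices, search_s = 0.06) {
  x <- signal$samples
  w <- round(search_s * signal$sampling_rate)
  n <- length(x)
  q <- s <- numeric(length(r_indices))
  for (b in seq_along(r_indices)) {
    r <- r_indices[b]
    lo <- max(0, r - w)
    hi <- min(n - 1, r + w)
    if (r - 1 >= lo) {
      seg <- x[(lo + 1):r] # 0-based lo..r-1
      q[b] <- lo + which.min(seg) - 1
    } else q[b] <- r
    if (r + 1 <= hi) {
      seg <- x[(r + 2):(hi + 1)] # 0-based r+1..hi
      s[b] <- r + which.min(seg)
    } else s[b] <- r
  }
  list(q = q, s = s)
}

#' Build a labeled segment-pair dataset from an annotated record
#'
#' Enumerates every valid detection center on the averaged timebase, labels
#' each against the annotations, and draws the requested number of pairs per
#' class uniformly at random (seeded, without replacement).
#'
#' @param record A [record_bundle()] with annotations.
#' @param n_i Averaging factor for the coarse timebase.
#' @param balance Named counts per class, e.g.
#'   `c(Q = 400, R = 400, S = 400, NONQRS = 400)`.
#' @param seed Integer seed for the class sampling.
#' @return An object of class `segment_dataset`: 56-column matrices
#'   `object` and `part`, factor `label`, 0-based `center_avg`/`center_raw`
#'   indices, plus `n_i` and `sampling_rate`.
#' @export
build_dataset <- function(record, n_i = 5L,
                          balance = c(Q = 100, R = 100, S = 100, NONQRS = 100),
                          seed = 1L) {
  stopifnot(inherits(record, "record_bundle"))
  if (is.null(record$annotations)) stop("record has no annotations", call. = FALSE)
  if (!all(CLASS_LEVELS %in% names(balance))) {
    stop("`balance` must name counts for Q, R, S and NONQRS", call. = FALSE)
  }
  sig <- record$signal
  fs <- sig$sampling_rate
  ann <- record$annotations
  if (is.null(ann$q_indices) || is.null(ann$s_indices)) {
    qs <- locate_qs(sig, ann$r_indices)
    ann <- beat_annotations(ann$r_indices, qs$q, qs$s)
  }
  sd <- difference_signal(sig)$samples
  sad <- average_difference(sig, n_i)$samples
  centers <- valid_centers(length(sig$samples), n_i)
  if (!length(centers)) stop("record too short to segment", call. = FALSE)
  cr <- center_raw_index(centers, n_i)
  lab <- label_center(cr, ann, fs, n_i = n_i)

  sel <- with_seed_(seed, function() {
    out <- integer(0)
    for (cls in CLASS_LEVELS) {
      pool <- which(!is.na(lab) & lab == cls)
      k <- as.integer(balance[[cls]])
      if (length(pool) < k) {
        stop(sprintf("insufficient eligible centers for class %s: %d available, %d requested",
                     cls, length(pool), k), call. = FALSE)
      }
      out <- c(out, pool[sample.int(length(pool), k)])
    }
    out
  })
  sel <- sort(sel)
  w <- extract_windows(sd, sad, centers[sel], n_i)
  structure(
    list(object = w$object, part = w$part,
         label = factor(lab[sel], levels = CLASS_LEVELS),
         center_avg = centers[sel], center_raw = cr[sel],
         n_i = as.integer(n_i), sampling_rate = fs),
    class = "segment_dataset"
  )
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat("<segment_dataset>", nrow(x$object), "pairs;",
      paste(sprintf("%s=%d", levels(x$label), tabulate(x$label, 4L)), collapse = " "),
      "\n")
  invisible(x)
}
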