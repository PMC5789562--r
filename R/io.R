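# Readers and writers: CSV signals with a JSON sidecar, plain-text beat
# annotations, JSON model containers, TSV metric reports. All sample
# indices on disk are 0-based.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a signal as two-column CSV with a JSON sidecar
#'
#' The CSV holds `index,mv` rows (0-based index, full precision); the
#' sidecar `<path>.json` records `record_id` and `sampling_rate`.
#'
#' @param signal A [raw_signal()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "raw_signal"))
  x <- signal$samples
  writeLines(c("index,mv",
               sprintf("%d,%.17g", seq_along(x) - 1L, x)), path)
  jsonlite::write_json(
    list(record_id = signal$record_id, sampling_rate = signal$sampling_rate),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signal from CSV
#'
#' Accepts one-column (samples only) or two-column (`index,mv`) CSV, with
#' an optional auto-detected header line. The sampling rate is taken from
#' the JSON sidecar written by [write_signal()] when present, else from
#' `sampling_rate`.
#'
#' @param path CSV path.
#' @param sampling_rate Fallback sampling rate, Hz.
#' @param record_id Fallback record identifier.
#' @return A [raw_signal()].
#' @export
read_signal <- function(path, sampling_rate = NULL, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fs <- sampling_rate
  id <- record_id
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path))
    if (is.null(fs)) fs <- meta$sampling_rate
    if (is.null(id)) id <- meta$record_id
  }
  if (is.null(fs)) stop("sampling rate unknown: no sidecar and no `sampling_rate` given",
                        call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signal file: ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  if (anyNA(first)) { # header line
    lines <- lines[-1L]
    fields <- fields[-1L]
  }
  if (!length(lines)) stop("signal file has a header but no data: ", path, call. = FALSE)
  ncol <- length(fields[[1L]])
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) stop("malformed numeric field in ", path, call. = FALSE)
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  if (ncol == 2L) {
    if (any(diff(m[, 1L]) <= 0)) stop("non-monotone sample index in ", path, call. = FALSE)
    samples <- m[, 2L]
  } else if (ncol == 1L) {
    samples <- m[, 1L]
  } else {
    stop("expected 1 or 2 CSV columns in ", path, call. = FALSE)
  }
  raw_signal(samples, fs, id)
}

#' Write beat annotations as two-column text
#'
#' One `sample_index label` row per landmark, labels in Q/R/S, sorted by
#' index.
#'
#' @param annotations A [beat_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "beat_annotations"))
  idx <- annotations$r_indices
  lab <- rep("R", length(idx))
  for (ql in list(c("q_indices", "Q"), c("s_indices", "S"))) {
    v <- annotations[[ql[1L]]]
    if (!is.null(v)) {
      idx <- c(idx, v)
      lab <- c(lab, rep(ql[2L], length(v)))
    }
  }
  o <- order(idx, lab)
  writeLines(sprintf("%d %s", round(idx[o]), lab[o]), path)
  invisible(path)
}

#' Read beat annotations from two-column text
#'
#' Whitespace- or comma-separated `sample_index label` rows. R rows become
#' `r_indices` (sorted, deduplicated); Q and S rows become the per-beat
#' landmarks; other labels are ignored (their count is reported via a
#' message). An empty file yields an empty annotation set.
#'
#' @param path Input path.
#' @return A [beat_annotations()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(beat_annotations(numeric(0)))
  parts <- strsplit(lines, "[,[:space:]]+")
  if (any(lengths(parts) < 2L)) stop("malformed annotation row in ", path, call. = FALSE)
  idx <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  lab <- toupper(vapply(parts, `[[`, "", 2L))
  if (anyNA(idx)) stop("non-numeric annotation index in ", path, call. = FALSE)
  if (any(idx < 0)) stop("negative annotation index in ", path, call. = FALSE)
  n_other <- sum(!lab %in% c("Q", "R", "S"))
  if (n_other > 0) message(n_other, " non-beat annotation rows ignored")
  grab <- function(l) {
    v <- sort(unique(idx[lab == l]))
    if (length(v)) v else NULL
  }
  r <- grab("R")
  beat_annotations(if (is.null(r)) numeric(0) else r, grab("Q"), grab("S"))
}

MODEL_FORMAT <- "qrscnn-model"
MODEL_VERSION <- 1L

#' Save a trained model as a self-describing JSON container
#'
#' Stores every weight and bias at full precision together with the
#' architecture block and training metadata; [load_model()] restores it
#' bit-faithfully (verified to < 1e-12 on the forward pass).
#'
#' @param model A [train_qrsnet()] model.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qrs_model"))
  pk <- lapply(model$params, function(p) {
    list(dim = if (is.null(dim(p))) length(p) else dim(p), data = as.numeric(p))
  })
  obj <- list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    spec = model$spec[c("input_length", "kernel_length", "n_maps", "pool",
                        "n_hidden", "n_classes")],
    n_i = model$n_i, sampling_rate = model$sampling_rate,
    train = list(eta0 = model$config$eta0,
                 decay_per_iter = model$config$decay_per_iter,
                 seed = model$config$seed, loss = model$config$loss,
                 epochs = if (is.null(model$log)) 0L else nrow(model$log),
                 iterations = model$iterations),
    params = pk
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Model file path.
#' @return A `qrs_model` (without the training log).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop("not a ", MODEL_FORMAT, " file: ", path, call. = FALSE)
  }
  spec <- do.call(network_spec, as.list(obj$spec))
  params <- lapply(obj$params, function(p) {
    d <- as.integer(p$dim)
    v <- as.numeric(p$data)
    if (prod(d) != length(v)) stop("corrupt parameter block", call. = FALSE)
    if (length(d) > 1L) array(v, d) else v
  })
  ref <- init_network_params(spec, seed = 1L)
  if (!identical(sort(names(params)), sort(names(ref)))) {
    stop("architecture mismatch: unexpected parameter set in ", path, call. = FALSE)
  }
  for (nm in names(ref)) {
    dref <- if (is.null(dim(ref[[nm]]))) length(ref[[nm]]) else dim(ref[[nm]])
    dgot <- if (is.null(dim(params[[nm]]))) length(params[[nm]]) else dim(params[[nm]])
    if (!identical(as.integer(dref), as.integer(dgot))) {
      stop(sprintf("architecture mismatch in `%s`: stored %s, spec requires %s",
                   nm, paste(dgot, collapse = "x"), paste(dref, collapse = "x")),
           call. = FALSE)
    }
  }
  params <- structure(params[names(ref)], class = "network_params")
  structure(
    list(spec = spec, params = params,
         config = train_config(eta0 = obj$train$eta0,
                               decay_per_iter = obj$train$decay_per_iter,
                               seed = obj$train$seed, loss = obj$train$loss),
         n_i = as.integer(obj$n_i), sampling_rate = obj$sampling_rate,
         iterations = obj$train$iterations, log = NULL),
    class = "qrs_model"
  )
}

#' Write a per-record metric table as TSV
#'
#' Columns mirror the conventional per-record report: record, total beats,
#' TP, FP, FN, Sen, PPR, DER, Acc (percentages rounded to 2 decimals).
#'
#' @param report Data frame from [evaluate_records()] or [snr_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(report, path) {
  out <- report
  for (cl in intersect(c("sen", "ppr", "der", "acc"), names(out))) {
    out[[cl]] <- round_half_up(out[[cl]], 2)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published per-record detection counts for metric validation
#'
#' Per-record total beats and TP/FP/FN counts, with the corresponding
#' published Sen/PPR/DER/Acc percentages, from a published CNN-based QRS
#' detector evaluation: 46 MLII records of the MIT-BIH arrhythmia database
#' (plus the count-pooled overall row) and the pooled INCART result. Used
#' to validate that [detection_metrics()] reproduces every printed value
#' from the printed counts.
#'
#' @param database `"mitbih"` or `"incart"`.
#' @return Data frame with columns record, total_beats, tp, fp, fn, sen,
#'   ppr, der, acc.
#' @export
reference_counts <- function(database = c("mitbih", "incart")) {
  database <- match.arg(database)
  f <- system.file("extdata",
                   paste0(database, "_reference_counts.tsv"),
                   package = "qrscnn", mustWork = TRUE)
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(record = "character"))
}
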