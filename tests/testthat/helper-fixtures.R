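# Shared fixtures. Models are trained once per test run and memoized:
# `small_model()` is a quick low-budget model for unit tests;
# `acceptance_model()` is the full 400-beat study-condition model.

.fixtures <- new.env(parent = emptyenv())

clean_config <- function(duration = 20, ...) {
  synth_config(duration = duration, hr_jitter = 0,
               baseline_wander_amplitude = 0, amp_jitter = 0, ...)
}

small_model <- function() {
  if (is.null(.fixtures$small_model)) {
    corpus <- make_training_corpus(n_qrs = 100, seed = 7)
    .fixtures$small_model <- train_qrsnet(
      corpus,
      config = train_config(max_epochs = 60, patience = 20, seed = 7))
  }
  .fixtures$small_model
}

acceptance_model <- function() {
  if (is.null(.fixtures$acceptance_model)) {
    corpus <- make_training_corpus(n_qrs = 400, seed = 7)
    .fixtures$acceptance_model <- train_qrsnet(corpus)
  }
  .fixtures$acceptance_model
}

held_out_records <- function(n = 10, duration = 60, seed_base = 100) {
  lapply(seq_len(n), function(k) {
    generate_record(synth_config(duration = duration), seed = seed_base + k,
                    record_id = sprintf("held-out-%02d", k))
  })
}

# Brute-force oracles, independent of the implementation under test.

oracle_conv1d <- function(X, W, b) {
  # X: len x cin matrix, W: taps x cin x cout, b: cout
  K <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  lo <- nrow(X) - K + 1
  out <- matrix(0, lo, cout)
  for (k in seq_len(cout)) for (t in seq_len(lo)) {
    acc <- b[k]
    for (i in seq_len(cin)) for (tau in seq_len(K)) {
      acc <- acc + X[t + tau - 1, i] * W[tau, i, k]
    }
    out[t, k] <- acc
  }
  out
}

oracle_block_means <- function(x, f) {
  nb <- length(x) %/% f
  out <- numeric(nb)
  for (j in seq_len(nb)) out[j] <- mean(x[((j - 1) * f + 1):(j * f)])
  out
}

# One-to-one matching oracle, valid when reference beats are separated by
# more than 2*tol: each prediction can then fall within tol of at most one
# reference, so TP = number of references with at least one prediction in
# range.
oracle_match_counts <- function(pred, ref, tol) {
  tp <- 0L
  for (r in ref) if (any(abs(pred - r) <= tol)) tp <- tp + 1L
  list(tp = tp, fp = length(pred) - tp, fn = length(ref) - tp)
}
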