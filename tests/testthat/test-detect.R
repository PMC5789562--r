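test_that("scan covers exactly the valid centers with unit-sum rows", {
  rec <- generate_record(synth_config(duration = 10), seed = 61)
  model <- small_model()
  stream <- scan_record(rec$signal, model)
  # bounds formula: 10 s at 360 Hz -> 3600 raw / 720 averaged samples;
  # object window needs 22 <= c <= 720 - 34; the part window is the binding
  # edge on the raw side only for shorter records
  expect_equal(stream$centers_avg, 22:686)
  expect_equal(rowSums(stream$posterior), rep(1, 665), tolerance = 1e-9)
  expect_equal(stream$effective_rate, 72)

  # determinism
  stream2 <- scan_record(rec$signal, model)
  expect_identical(stream$posterior, stream2$posterior)

  expect_error(scan_record(raw_signal(rnorm(100), 360), model), "too short")
})

test_that("all-zero parameters yield uniform posteriors everywhere", {
  rec <- generate_record(synth_config(duration = 5), seed = 62)
  model <- small_model()
  zero <- model
  for (nm in names(zero$params)) zero$params[[nm]][] <- 0
  stream <- scan_record(rec$signal, zero)
  expect_true(all(abs(stream$posterior - 0.25) < 1e-12))
  # and with no posterior above threshold the detection set is empty
  det <- decide_detections(stream)
  expect_length(det$r_indices, 0)
})

test_that("decision logic: run argmax location and refractory suppression", {
  model <- small_model()
  mk_stream <- function(r_post, centers_avg) {
    post <- cbind(Q = 0, R = r_post, S = 0, NONQRS = 1 - r_post)
    structure(list(centers_avg = centers_avg,
                   centers_raw = centers_avg * 5 + 2,
                   posterior = post, effective_rate = 72,
                   n_i = 5L, sampling_rate = 360),
              class = "posterior_stream")
  }
  # single run [0.6, 0.9, 0.7] at centers 100:102 -> event at center 101
  s <- mk_stream(c(rep(0, 5), 0.6, 0.9, 0.7, rep(0, 5)), 95:107)
  det <- decide_detections(s)
  expect_equal(det$r_indices, 101 * 5 + 2)
  expect_equal(det$confidence, 0.9)

  # two runs 0.15 s apart (0.15 * 72 ~ 11 averaged samples): weaker one dies
  r <- rep(0, 40)
  r[5] <- 0.9; r[16] <- 0.8
  s2 <- mk_stream(r, 100:139)
  det2 <- decide_detections(s2, refractory_s = 0.2)
  expect_equal(det2$r_indices, (100 + 4) * 5 + 2)
  # with a refractory shorter than the gap both survive
  det3 <- decide_detections(s2, refractory_s = 0.1)
  expect_length(det3$r_indices, 2)
})

test_that("refractory constraint is never violated end-to-end", {
  model <- small_model()
  for (s in 63:65) {
    rec <- generate_record(synth_config(duration = 30), seed = s)
    noisy <- add_gaussian_noise(rec$signal, 10, seed = s)
    det <- detect_beats(noisy, model)
    if (length(det$r_indices) > 1) {
      expect_true(all(diff(det$r_indices) >= 0.2 * 360))
    }
  }
})

test_that("peak refinement lands on the apex, is idempotent, and keeps flat signals fixed", {
  rec <- generate_record(clean_config(duration = 20), seed = 66)
  model <- small_model()
  stream <- scan_record(rec$signal, model)
  det <- decide_detections(stream)
  # perturb detections a few samples off the apex
  shifted <- det
  shifted$r_indices <- det$r_indices - 3
  ref <- refine_to_peak(shifted, rec$signal)
  for (k in seq_along(ref$r_indices)) {
    d <- abs(rec$annotations$r_indices - ref$r_indices[k])
    expect_lte(min(d), 1)
  }
  # idempotent
  ref2 <- refine_to_peak(ref, rec$signal)
  expect_identical(ref$r_indices, ref2$r_indices)

  # flat signal: no strict improvement anywhere -> indices unchanged
  flatsig <- raw_signal(rep(0.5, 4000), 360)
  flat_det <- structure(list(r_indices = c(100, 900), confidence = c(1, 1),
                             sampling_rate = 360, threshold = 0.5,
                             refractory_s = 0.2),
                        class = "detection_result")
  expect_equal(refine_to_peak(flat_det, flatsig)$r_indices, c(100, 900))
})

test_that("a trained model recovers nearly all beats on held-out clean records", {
  model <- small_model()
  recs <- held_out_records(n = 2, duration = 30, seed_base = 500)
  rows <- evaluate_records(recs, model)
  pooled <- rows[rows$record == "overall", ]
  expect_gte(pooled$sen, 95)
  expect_gte(pooled$ppr, 95)
})
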