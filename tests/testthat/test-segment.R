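test_that("window geometry: 22 before + center + 33 after on both timebases", {
  set.seed(41)
  x <- rnorm(600)
  sd <- difference_signal(x, 360)
  sad <- average_difference(x, 5, sampling_rate = 360)
  p <- extract_pair(sd, sad, 22)
  expect_length(p$object_window, 56)
  expect_length(p$part_window, 56)
  expect_equal(p$object_window, sad$samples[1:56]) # sad[0..55], 0-based
  expect_equal(p$center_raw_index, 112)
  expect_equal(p$part_window, sd$samples[(112 - 22 + 1):(112 + 33 + 1)])
})

test_that("windows at the last valid center end exactly at the usable edge", {
  set.seed(42)
  x <- rnorm(300) # len_avg = 60 at n_i = 5
  sd <- difference_signal(x, 360)
  sad <- average_difference(x, 5, sampling_rate = 360)
  centers <- qrscnn:::valid_centers(300, 5)
  # by hand: object needs c+33 <= 59 -> c <= 26; part needs 5c+2+33 <= 299
  expect_equal(range(centers), c(22, 26))
  last <- max(centers)
  p <- extract_pair(sd, sad, last)
  expect_equal(p$object_window[56], sad$samples[60])
  expect_error(extract_pair(sd, sad, last + 1), "out of bounds")
  expect_error(extract_pair(sd, sad, 21), "out of bounds")
})

test_that("a 56-sample window spans 0.16 s fine and 0.78 s coarse at 360 Hz", {
  span <- window_span_s(360, 5)
  expect_equal(round(span[["part"]], 2), 0.16)
  expect_equal(round(span[["object"]], 2), 0.78)
})

test_that("extraction is translation-consistent under one-averaged-sample shifts", {
  set.seed(43)
  x <- rnorm(1000)
  sad1 <- average_difference(x, 5, sampling_rate = 360)$samples
  sad2 <- average_difference(x[-(1:5)], 5, sampling_rate = 360)$samples
  # away from the out[0] = 0 convention cell, shifting the record by n_i raw
  # samples shifts the averaged timebase by exactly one index
  expect_equal(sad2[2:(length(sad2))], sad1[3:(length(sad1))])
})

test_that("labeling follows the R / Q / S / non-QRS tolerance rules", {
  cfg <- clean_config(duration = 20)
  rec <- generate_record(cfg, seed = 44)
  ann <- rec$annotations
  fs <- 360
  r1 <- ann$r_indices[3]
  expect_equal(label_center(r1, ann, fs), "R")
  expect_equal(label_center(ann$q_indices[3], ann, fs), "Q")
  expect_equal(label_center(ann$s_indices[3], ann, fs), "S")
  expect_equal(label_center(r1 + round(0.5 * fs), ann, fs), "NONQRS")
  # ambiguous band between the QRS zone and the 0.2 s exclusion radius
  expect_true(is.na(label_center(r1 + round(0.1 * fs), ann, fs)))
})

test_that("one-hot targets have exactly one active component", {
  m <- one_hot(c("Q", "R", "S", "NONQRS"))
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(rowSums(m), rep(1, 4))
  expect_equal(diag(m), rep(1, 4))
  expect_error(one_hot("X"), "unknown class")
})

test_that("dataset honors requested class counts, determinism and peak placement", {
  rec <- generate_record(clean_config(duration = 60), seed = 45)
  bal <- c(Q = 10, R = 10, S = 10, NONQRS = 10)
  ds <- build_dataset(rec, balance = bal, seed = 3)
  expect_equal(nrow(ds$object), 40)
  expect_equal(unname(tabulate(ds$label, 4)), rep(10L, 4))
  ds2 <- build_dataset(rec, balance = bal, seed = 3)
  expect_identical(ds$part, ds2$part)
  expect_identical(ds$label, ds2$label)

  # every R window's max |difference| lies within the central 20 samples
  for (j in which(ds$label == "R")) {
    pos <- which.max(abs(ds$part[j, ]))
    # center sits at window position 23; the steepest QRS slope lies within
    # one R-tolerance (5 raw samples) plus one R-width (~8 samples) of it
    expect_true(abs(pos - 23) <= 13)
  }

  expect_error(build_dataset(rec, balance = c(Q = 1e5, R = 10, S = 10, NONQRS = 10),
                             seed = 1),
               "class Q")
})

test_that("derived Q/S landmarks recover the generator's ground truth", {
  rec <- generate_record(clean_config(duration = 20), seed = 46)
  qs <- locate_qs(rec$signal, rec$annotations$r_indices)
  # the composite-waveform trough sits a few samples outside the Q/S
  # component center because the R flank overlaps it; allow that shift
  expect_true(all(abs(qs$q - rec$annotations$q_indices) <= 6))
  expect_true(all(abs(qs$s - rec$annotations$s_indices) <= 6))
  expect_true(all(qs$q < rec$annotations$r_indices))
  expect_true(all(qs$s > rec$annotations$r_indices))
})
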