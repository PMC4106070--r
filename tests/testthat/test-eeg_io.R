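# Recording I/O, segmentation and train/test splitting.

test_that("delimited recordings round-trip through write and read", {
  set.seed(7)
  rec <- recording(matrix(rnorm(2 * 10), 2, 10), fs = 5,
                   seizure_intervals = cbind(0.4, 1.2))
  sig <- tempfile(fileext = ".txt")
  ann <- tempfile(fileext = ".txt")
  write_recording(rec, sig, ann)
  back <- read_recording(sig, "delimited", fs = 5, intervals = ann)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$seizure_intervals, rec$seizure_intervals, tolerance = 1e-12)
  expect_equal(nrow(back$data), 2L)
  expect_equal(ncol(back$data), 10L)
  expect_equal(ncol(back$data) / back$fs, 2)     # 2 s duration

  # comma dialect is auto-detected
  csv <- tempfile(fileext = ".csv")
  writeLines(c("1,2,3,4", "5,6,7,8"), csv)
  rec2 <- read_recording(csv, "delimited", fs = 2)
  expect_equal(rec2$data, rbind(1:4, 5:8))
})

test_that("malformed delimited input and invalid intervals are rejected", {
  bad <- tempfile()
  writeLines(c("1 2 3", "4 5"), bad)
  expect_error(read_recording(bad, "delimited", fs = 1),
               "inconsistent row lengths")
  ok <- tempfile()
  writeLines(c("1 2 3 4", "5 6 7 8"), ok)
  expect_error(read_recording(ok, "delimited"), "fs is required")
  expect_error(read_recording(ok, "delimited", fs = 2,
                              intervals = cbind(-1, 3)),
               "within")
  expect_error(recording(matrix(c(1, NA), 1, 2), fs = 1), "finite")
  expect_error(recording(matrix(1:8, 2, 4), fs = 2,
                         seizure_intervals = rbind(c(0, 1.5), c(1, 2))),
               "overlap")
})

test_that("EDF files round-trip within quantisation error", {
  set.seed(11)
  fs <- 32L
  rec <- recording(matrix(50 * rnorm(3 * fs * 2), 3, fs * 2), fs = fs,
                   channel_labels = c("F3", "C3", "O1"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, "edf")
  expect_equal(back$fs, fs)
  expect_equal(back$channel_labels, rec$channel_labels)
  qstep <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  for (ch in 1:3) {
    expect_lt(max(abs(back$data[ch, ] - rec$data[ch, ])), 2 * qstep[ch] + 1e-9)
  }
})

test_that("EDF with mismatched per-channel sample counts is rejected", {
  rec <- recording(matrix(rnorm(2 * 64), 2, 64), fs = 32)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path, samples_per_record = c(32L, 16L))
  expect_error(read_recording(path, "edf"), "samples per record")
})

test_that("nonseizure time is tiled without overlap", {
  # 10080 s at fs = 2, no seizure annotations, 5 s windows
  rec <- recording(matrix(0, 2, 10080 * 2), fs = 2)
  segs <- segment_recording(rec, window_s = 5)
  expect_length(segs, 2016L)
  expect_true(all(segment_labels(segs) == "nonseizure"))
  starts <- vapply(segs, function(s) s$start_s, numeric(1))
  expect_equal(starts, seq(0, by = 5, length.out = 2016))
})

test_that("seizure windows slide with the configured overlap", {
  rec <- recording(matrix(0, 2, 25 * 4), fs = 4,
                   seizure_intervals = cbind(0, 20))
  segs <- segment_recording(rec, window_s = 5, seizure_overlap_frac = 0.5)
  seiz <- segs[segment_labels(segs) == "seizure"]
  expect_length(seiz, 7L)
  expect_equal(vapply(seiz, function(s) s$start_s, numeric(1)),
               seq(0, 15, by = 2.5))
  # an interval exactly one window long yields a single segment
  rec2 <- recording(matrix(0, 2, 10 * 4), fs = 4,
                    seizure_intervals = cbind(2, 7))
  segs2 <- segment_recording(rec2, window_s = 5, seizure_overlap_frac = 0)
  expect_length(which(segment_labels(segs2) == "seizure"), 1L)
})

test_that("no emitted window straddles a seizure-interval boundary", {
  set.seed(3)
  ints <- rbind(c(12.3, 31.7), c(50.2, 64.9))
  rec <- recording(matrix(rnorm(2 * 100 * 8), 2, 100 * 8), fs = 8,
                   seizure_intervals = ints)
  segs <- segment_recording(rec, window_s = 5, seizure_overlap_frac = 0.3)
  for (s in segs) {
    lo <- s$start_s
    hi <- s$start_s + 5
    inside <- any(lo >= ints[, 1] - 1e-9 & hi <= ints[, 2] + 1e-9)
    outside <- all(hi <= ints[, 1] + 1e-9 | lo >= ints[, 2] - 1e-9)
    if (s$label == "seizure") expect_true(inside) else expect_true(outside)
  }
  expect_error(segment_recording(rec, window_s = 1000), "longer than")
})

test_that("train/test split is balanced, disjoint and seed-deterministic", {
  segs <- fake_segments(1000, 4000)
  sp <- split_train_test(segs, n_train_per_class = 750, seed = 42)
  expect_length(sp$train, 1500L)
  expect_length(sp$test, 3500L)
  expect_equal(sum(segment_labels(sp$train) == "seizure"), 750L)
  expect_equal(sum(segment_labels(sp$train) == "nonseizure"), 750L)

  key <- function(s) paste(s$label, s$start_s)
  all_keys <- sort(vapply(segs, key, character(1)))
  got_keys <- sort(vapply(c(sp$train, sp$test), key, character(1)))
  expect_equal(got_keys, all_keys)                 # union preserved
  expect_length(intersect(vapply(sp$train, key, character(1)),
                          vapply(sp$test, key, character(1))), 0L)

  sp2 <- split_train_test(segs, n_train_per_class = 750, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(segs, n_train_per_class = 750, seed = 43)
  expect_false(identical(sp, sp3))

  expect_error(split_train_test(fake_segments(900, 4000),
                                n_train_per_class = 1000, seed = 1),
               "fewer than")
})
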