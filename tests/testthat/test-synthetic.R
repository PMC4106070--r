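# Synthetic EEG generator: determinism, spectral structure, artifacts.

test_that("background generation is deterministic and correctly scaled", {
  sc <- synth_config(n_channels = 4, fs = 64, background_amp = 12, seed = 1)
  a <- gen_background(sc, 2, seed = 5)
  b <- gen_background(sc, 2, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, gen_background(sc, 2, seed = 6)))

  sc0 <- synth_config(n_channels = 3, background_amp = 0)
  expect_equal(gen_background(sc0, 1, seed = 1),
               matrix(0, 3, 256))

  # per-channel sample variance within 20% of the configured variance
  long <- gen_background(sc, 90, seed = 9)
  v <- apply(long, 1, var)
  expect_true(all(abs(v - 12^2) / 12^2 < 0.2))
})

test_that("seizure oscillation is coherent, in-band, and vanishes at zero amplitude", {
  sc <- synth_config(n_channels = 4, fs = 128, background_amp = 5,
                     seizure_band = c(8, 13), seizure_amp = 60,
                     coupled_fraction = 1)
  x <- gen_seizure_activity(sc, 10, seed = 3)

  # oracle: smoothed-periodogram magnitude-squared coherence via spec.pgram,
  # averaged over the in-band bins weighted by where the seizure power sits
  # (the drifting oscillation does not visit every bin of the band)
  ts_all <- stats::ts(t(x), frequency = sc$fs)
  sp <- stats::spec.pgram(ts_all, spans = c(11, 11), taper = 0.1,
                          plot = FALSE, detrend = TRUE)
  in_band <- sp$freq >= 8 & sp$freq <= 13
  w <- rowMeans(sp$spec)[in_band]
  wmean <- apply(sp$coh[in_band, , drop = FALSE], 2,
                 function(coh) sum(coh * w) / sum(w))
  expect_gt(min(wmean), 0.9)

  # spectral peak of every coupled channel lies inside the band
  for (ch in 1:4) {
    pg <- stats::spec.pgram(stats::ts(x[ch, ], frequency = sc$fs),
                            plot = FALSE, detrend = TRUE)
    fpeak <- pg$freq[which.max(pg$spec)]
    expect_gte(fpeak, 8)
    expect_lte(fpeak, 13)
  }

  sc0 <- synth_config(n_channels = 4, fs = 128, background_amp = 5,
                      seizure_band = c(8, 13), seizure_amp = 0,
                      coupled_fraction = 1)
  z <- gen_seizure_activity(sc0, 2, seed = 7)
  attr(z, "coupled_channels") <- NULL
  expect_equal(z, gen_background(sc0, 2, seed = 7))
})

test_that("EMG bursts are rare, large and localised", {
  sc <- synth_config(n_channels = 4, artifact_rate = 0)
  x <- gen_background(sc, 5, seed = 2)
  expect_identical(inject_emg_artifacts(x, sc, seed = 4)$data, x)

  sc50 <- synth_config(n_channels = 4, background_amp = 10,
                       artifact_rate = 120, artifact_amp_mult = 50)
  res <- inject_emg_artifacts(x, sc50, seed = 8)
  expect_gt(nrow(res$log), 0)
  expect_gte(max(abs(res$data)), 40 * sc50$background_amp)
  # untouched channels/samples stay identical
  expect_true(any(res$data == x))
})

test_that("bursts create cross-power outliers between the affected channels", {
  sc <- synth_config(n_channels = 6, background_amp = 10,
                     artifact_rate = 40, artifact_amp_mult = 50,
                     artifact_dur_s = 0.4)
  x <- gen_background(sc, 5, seed = 21)
  res <- inject_emg_artifacts(x, sc, seed = 22)
  counts <- table(res$log$onset_s)
  multi <- names(counts)[counts >= 2][1]
  expect_false(is.na(multi))                     # an event hit >= 2 channels
  chans <- res$log$channel[res$log$onset_s == multi][1:2]
  m <- cross_power_matrix(res$data, band("beta"), sc$fs)
  expect_gt(m[chans[1], chans[2]], 10 * median(m))
})

test_that("labelled datasets have exact counts, determinism and class contrast", {
  sc <- synth_config(n_channels = 4, seed = 33)
  segs <- make_labeled_dataset(sc, 30, 50)
  expect_length(segs, 80L)
  expect_equal(sum(segment_labels(segs) == "seizure"), 30L)
  expect_equal(sum(segment_labels(segs) == "nonseizure"), 50L)
  expect_identical(segs, make_labeled_dataset(sc, 30, 50))
  expect_error(make_labeled_dataset(sc, 0, 10), "positive")

  f <- cross_power_features(segs, list(band("alpha")), sc$fs)[[1]]
  lab <- segment_labels(segs)
  expect_gt(mean(f[lab == "seizure", ]), mean(f[lab == "nonseizure", ]))
})

test_that("class separation shrinks as the seizure amplitude approaches background", {
  sep_at <- function(amp) {
    # expected separation: average the pooled FDR over a few seeds,
    # without artifacts, to isolate the amplitude dial
    mean(vapply(1:3, function(seed) {
      sc <- synth_config(n_channels = 4, seizure_amp = amp,
                         artifact_rate = 0, seed = 55 + seed)
      segs <- make_labeled_dataset(sc, 40, 40, artifacts = FALSE)
      # log scale, as consumed by the network: raw pooled FDR saturates
      # because class mean gap and spread both grow ~ amp^4
      f <- log1p(cross_power_features(segs, list(band("alpha")), sc$fs)[[1]])
      lab <- segment_labels(segs)
      fdr_score(as.vector(f[lab == "seizure", ]),
                as.vector(f[lab == "nonseizure", ]))
    }, numeric(1)))
  }
  fdrs <- vapply(c(25, 10, 3), sep_at, numeric(1))
  expect_true(all(diff(fdrs) < 0))
})

test_that("artifacts hit both classes at comparable rates", {
  sc <- synth_config(n_channels = 4, artifact_rate = 30, seed = 77)
  segs <- make_labeled_dataset(sc, 80, 80)
  lab <- segment_labels(segs)
  # a burst at 20x background is detectable as an extreme peak
  has_burst <- vapply(segs, function(s) {
    max(abs(s$data)) > 8 * sc$background_amp + sc$seizure_amp
  }, logical(1))
  rate_s <- mean(has_burst[lab == "seizure"])
  rate_n <- mean(has_burst[lab == "nonseizure"])
  expect_gt(rate_s, 0.5 * rate_n)
  expect_lt(rate_s, 2 * rate_n)
})
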