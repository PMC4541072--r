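test_that("waveform synthesis respects construction truth in the degenerate case", {
  p <- context_profile("t", n_elements_mean = 1, element_duration_ms = 100,
                       center_freq_hz = 2000, bandwidth_hz = 500,
                       tonality = 0.6, dispersion_scale = 0)
  rec <- synthesize_call(p, seed = 1)
  truth <- attr(rec, "elements")
  expect_equal(nrow(truth$intervals), 1)
  expect_lt(abs(diff(truth$intervals[1, ]) * 1000 - 100), 3)

  p3 <- context_profile("t", n_elements_mean = 3, element_duration_ms = 40,
                        center_freq_hz = 2000, bandwidth_hz = 500,
                        tonality = 0.6, dispersion_scale = 0)
  expect_equal(nrow(attr(synthesize_call(p3, seed = 2), "elements")$intervals),
               3)
})

test_that("synthesis rejects frequencies above Nyquist", {
  p <- context_profile("t", 1, 50, center_freq_hz = 12000,
                       bandwidth_hz = 1000, tonality = 0.5)
  expect_error(synthesize_call(p, sample_rate_hz = 22050), "Nyquist|twice")
})

test_that("fixed seed fixes waveform and feature-table output bit-for-bit", {
  p <- waveform_profiles("female")$snake
  r1 <- synthesize_call(p, seed = 11)
  r2 <- synthesize_call(p, seed = 11)
  expect_identical(r1$samples, r2$samples)
  expect_false(identical(r1$samples, synthesize_call(p, seed = 12)$samples))

  spec <- population_spec(blob_profiles(), 4, 3, seed = 5)
  expect_identical(synthesize_feature_table(spec),
                   synthesize_feature_table(spec))
})

test_that("mean peak frequency of generated calls is recovered by extraction", {
  # female terrestrial mean peak frequency 2374 Hz; tolerance two 21.5-Hz bins
  p <- waveform_profiles("female")$terrestrial
  pf <- vapply(1:30, function(i) {
    rec <- synthesize_call(p, seed = 300 + i)
    extract_features(rec, attr(rec, "elements"))$peak_frequency_hz
  }, numeric(1))
  expect_lt(abs(mean(pf) - 2374), 2 * 22050 / 1024)
})

test_that("tonality orders extracted Wiener entropy", {
  mk <- function(tonality) {
    p <- context_profile("t", 1, 150, center_freq_hz = 4000,
                         bandwidth_hz = 7600, tonality = tonality,
                         dispersion_scale = 0)
    rec <- synthesize_call(p, seed = 77)
    extract_features(rec, attr(rec, "elements"))$wiener_entropy
  }
  expect_gt(mk(0), mk(1))
})

test_that("degenerate feature draws reproduce the context means exactly", {
  spec <- population_spec(blob_profiles()[1:2], 3, 4, individual_sd = 0,
                          dispersion = 0, seed = 1)
  tab <- synthesize_feature_table(spec)
  for (p in blob_profiles()[1:2]) {
    sub <- tab[tab$context == p$context, vars10]
    expect_true(all(apply(sub, 1, function(r) all(r == p$mean))))
  }
})

test_that("feature generator matches the reference table distributions", {
  # terrestrial mean element count 1.4; n = 50/context as in a field batch
  profs <- feature_profiles("female")
  tab <- synthesize_feature_table(population_spec(profs, 10, 5, seed = 21))
  terr <- tab$n_elements[tab$context == "terrestrial"]
  d <- vervet_descriptives("female")
  row <- d[d$variable == "n_elements" & d$context == "terrestrial", ]
  sd_call <- row$sem * sqrt(row$n)
  expect_lt(abs(mean(terr) - 1.4), 3 * sd_call / sqrt(length(terr)))

  # per-context sample SD ~ SEM * sqrt(n) within 20% at large n
  tab2 <- synthesize_feature_table(
    population_spec(profs["snake"], 1, 500, seed = 22))
  row2 <- d[d$variable == "peak_frequency_hz" & d$context == "snake", ]
  expect_lt(abs(sd(tab2$peak_frequency_hz) / (row2$sem * sqrt(row2$n)) - 1),
            0.2)
})

test_that("feature-table means converge to the specified means", {
  profs <- blob_profiles()[1]
  tab <- synthesize_feature_table(
    population_spec(profs, 1, 10000, seed = 33))
  mu <- profs[[1]]$mean
  got <- colMeans(tab[, vars10])
  expect_true(all(abs(got - mu) / mu < 0.01))
})

test_that("extracted features preserve the generating rank order across contexts", {
  profs <- waveform_profiles("male", dispersion_scale = 0.3)
  pf_means <- vapply(profs, function(p) {
    mean(vapply(1:8, function(i) {
      rec <- synthesize_call(p, seed = 400 + i)
      extract_features(rec, attr(rec, "elements"))$peak_frequency_hz
    }, numeric(1)))
  }, numeric(1))
  centers <- vapply(profs, `[[`, numeric(1), "center_freq_hz")
  expect_identical(order(pf_means), order(centers))
})

test_that("WAV and label-track round trips preserve the call", {
  p <- waveform_profiles("female")$aerial
  rec <- synthesize_call(p, seed = 9)
  wav <- withr::local_tempfile(fileext = ".wav")
  lbl <- withr::local_tempfile(fileext = ".txt")
  write_wav(rec, wav)
  back <- read_wav(wav)
  expect_equal(back$sample_rate_hz, rec$sample_rate_hz)
  expect_equal(back$samples, rec$samples, tolerance = 1e-4)
  truth <- attr(rec, "elements")
  write_label_track(truth, lbl)
  back_el <- read_label_track(lbl)
  expect_equal(back_el$intervals, truth$intervals, tolerance = 1e-9)
  expect_equal(back_el$main_index, truth$main_index)
})
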