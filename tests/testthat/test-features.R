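fs <- 22050
bin_hz <- fs / 1024

test_that("high-pass filter removes the stopband and keeps the passband", {
  lo <- tone_recording(50, 1)
  hi <- tone_recording(1000, 1)
  # steady-state RMS: central half, excluding filter edge transients
  rms <- function(r) {
    n <- length(r$samples)
    sqrt(mean(r$samples[(n %/% 4):(3 * n %/% 4)]^2))
  }
  expect_lt(rms(highpass_filter(lo)) / rms(lo), 0.01)
  expect_lt(abs(rms(highpass_filter(hi)) / rms(hi) - 1), 0.11)

  mix <- call_recording(lo$samples + hi$samples, fs)
  out <- highpass_filter(mix)
  spec <- Mod(fft(out$samples))[1:(length(out$samples) %/% 2)]
  f_peak <- (which.max(spec) - 1) * fs / length(out$samples)
  expect_lt(abs(f_peak - 1000), 5)
  expect_error(highpass_filter(tone_recording(100), cutoff_hz = 12000),
               "Nyquist")
})

test_that("resampling to 22.05 kHz halves 44.1 kHz input and preserves tones", {
  n <- 44100
  rec44 <- call_recording(sin(2 * pi * 1000 * (0:(n - 1)) / 44100), 44100)
  out <- resample_to_22k05(rec44)
  expect_equal(out$sample_rate_hz, 22050)
  expect_lte(abs(length(out$samples) - round(n / 2)), 1)
  spec <- Mod(fft(out$samples))[1:(length(out$samples) %/% 2)]
  f_peak <- (which.max(spec) - 1) * 22050 / length(out$samples)
  expect_lt(abs(f_peak - 1000), 5)

  rec22 <- tone_recording(1000)
  expect_identical(resample_to_22k05(rec22), rec22)
  expect_error(resample_to_22k05(call_recording(rnorm(100), 16000)),
               "upsample")
})

test_that("envelope segmentation recovers burst boundaries", {
  burst <- function(dur_s) {
    x <- sin(2 * pi * 2000 * (0:(round(dur_s * fs) - 1)) / fs)
    nr <- round(0.005 * fs)
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[1:nr] <- x[1:nr] * ramp
    x[(length(x) - nr + 1):length(x)] <- rev(ramp) * x[(length(x) - nr + 1):length(x)]
    x
  }
  gap <- numeric(round(0.1 * fs))
  x <- c(gap, burst(0.04), gap, burst(0.04), gap, burst(0.04), gap)
  el <- segment_elements(call_recording(x, fs))
  expect_equal(nrow(el$intervals), 3)
  starts_true <- (length(gap) + (0:2) * (round(0.04 * fs) + length(gap))) / fs
  expect_true(all(abs(el$intervals[, 1] - starts_true) < 0.005))
  expect_true(all(abs(el$intervals[, 2] - (starts_true + 0.04)) < 0.005))

  expect_error(segment_elements(call_recording(numeric(1000), fs)),
               class = "vocalarm_no_elements")
  one <- segment_elements(tone_recording(3000, 0.2))
  expect_equal(nrow(one$intervals), 1)
  expect_equal(one$main_index, 1)
})

test_that("spectrogram follows the fixed analysis geometry", {
  expect_equal(nrow(call_spectrogram(call_recording(rnorm(1024), fs))$magnitudes),
               1)
  sp <- call_spectrogram(tone_recording(1000, 0.3))
  expect_equal(sp$freq_bins_hz[2] - sp$freq_bins_hz[1], bin_hz)
  peaks <- apply(sp$magnitudes, 1, function(m) sp$freq_bins_hz[which.max(m)])
  expect_true(all(abs(peaks - 1000) <= bin_hz))
  n <- 5000
  expect_equal(nrow(call_spectrogram(call_recording(rep(1e-12, n), fs))$magnitudes),
               floor((n - 1024) / 64) + 1)
  expect_error(call_spectrogram(call_recording(rnorm(100), fs)), "1024")
})

test_that("Wiener entropy matches hand-computed oracles", {
  expect_equal(wiener_entropy(rep(2, 100)), 1.0)
  expect_equal(wiener_entropy(c(5, rep(0, 99))), 0.0)
  expect_equal(wiener_entropy(c(1, 1, 4)), 4^(1 / 3) / 2, tolerance = 1e-12)
  expect_equal(round(wiener_entropy(c(1, 1, 4)), 4), 0.7937)
  expect_true(is.na(wiener_entropy(numeric(3))))
})

test_that("spectral quartiles follow the cumulative-magnitude convention", {
  freqs <- (0:511) * bin_hz
  q <- spectral_quartiles(rep(1, 512), freqs)
  expect_equal(unname(q), c(127 * bin_hz, 255 * bin_hz))
  expect_lte(abs(q[["q1_hz"]] - 11025 / 4), bin_hz + 1e-9)
  expect_lte(abs(q[["q2_hz"]] - 11025 / 2), bin_hz + 1e-9)

  m <- numeric(512); m[100] <- 3
  expect_equal(unname(spectral_quartiles(m, freqs)), rep(freqs[100], 2))

  m2 <- numeric(512); m2[c(50, 200)] <- 1   # two equal lines: both quartiles
  expect_equal(unname(spectral_quartiles(m2, freqs)), rep(freqs[50], 2))
})

test_that("peak-frequency statistics: jump, constancy, and range", {
  rec <- tone_recording(2000, 0.3)
  el <- element_set(matrix(c(0.02, 0.28), 1))
  sp <- call_spectrogram(rec)
  st <- peak_frequency_stats(sp, el)
  expect_equal(st$pf_jump_hz, 0)
  expect_lt(abs(st$mean_pf_hz - 2000), bin_hz)

  # alternating 1000/3000 Hz tone: maximal jump ~ 2000 Hz
  blocks <- rep(c(1000, 3000), each = round(0.05 * fs), times = 3)
  x <- sin(2 * pi * cumsum(blocks) / fs)
  alt <- call_recording(x, fs)
  el2 <- element_set(matrix(c(0.02, length(blocks) / fs - 0.02), 1))
  st2 <- peak_frequency_stats(call_spectrogram(alt), el2)
  expect_lt(abs(st2$pf_jump_hz - 2000), 2 * bin_hz)

  nb <- shaped_noise_recording(1800, 2200, seed = 4)
  el3 <- element_set(matrix(c(0.02, 0.28), 1))
  st3 <- peak_frequency_stats(call_spectrogram(nb), el3)
  expect_lte(st3$frequency_range_hz, 400 + 4 * bin_hz)
})

test_that("FP1 picks the lowest dominant band", {
  el <- element_set(matrix(c(0.02, 0.18), 1))
  sp <- call_spectrogram(tone_recording(1000))
  f1 <- dominant_band_fp1(sp, el)
  expect_lt(abs(f1$fp1_mean_hz - 1000), bin_hz)
  st <- peak_frequency_stats(sp, el)
  expect_lte(abs(f1$fp1_mean_hz - st$mean_pf_hz), bin_hz)

  two <- call_recording(
    sin(2 * pi * 800 * (0:4409) / fs) + sin(2 * pi * 2500 * (0:4409) / fs), fs)
  f2 <- dominant_band_fp1(call_spectrogram(two),
                          element_set(matrix(c(0.02, 0.18), 1)))
  expect_lt(abs(f2$fp1_mean_hz - 800), 2 * bin_hz)

  wn <- call_recording(withr::with_seed(5, rnorm(4410)), fs)
  f3 <- dominant_band_fp1(call_spectrogram(wn),
                          element_set(matrix(c(0.02, 0.18), 1)))
  expect_true(is.finite(f3$fp1_mean_hz))
})

test_that("extract_features composes the measurements deterministically", {
  p <- context_profile("t", 3, 40, center_freq_hz = 2500, bandwidth_hz = 800,
                       tonality = 0.6, dispersion_scale = 0)
  rec <- synthesize_call(p, seed = 12)
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
  expect_equal(f1$n_elements, 3)

  tone <- tone_recording(990, 0.1)
  ft <- extract_features(tone, element_set(matrix(c(0, 0.1), 1)))
  expect_lt(abs(ft$element_duration_ms - 100), 6)
  expect_lte(abs(ft$first_quartile_hz - ft$peak_frequency_hz), bin_hz)
  expect_lte(abs(ft$second_quartile_hz - ft$peak_frequency_hz), bin_hz)
})

test_that("quartile ordering and entropy ordering invariants hold", {
  tab <- extract_feature_table(
    synthesize_calls(waveform_profiles("female"), 4, seed = 50))
  expect_true(all(tab$first_quartile_hz <= tab$second_quartile_hz))
  expect_true(all(tab$second_quartile_hz <= 11025))
  expect_true(all(tab$wiener_entropy >= 0 & tab$wiener_entropy <= 1))

  ent <- function(rec) {
    sp <- call_spectrogram(rec)
    mean(apply(sp$magnitudes[, sp$freq_bins_hz >= 100], 1, wiener_entropy),
         na.rm = TRUE)
  }
  e_tone <- ent(tone_recording(2000, 0.15))
  e_band <- ent(shaped_noise_recording(800, 3000, 0.15, seed = 6,
                                       floor_rel = 0.01))
  e_white <- ent(shaped_noise_recording(100, 11000, 0.15, seed = 6))
  expect_lt(e_tone, e_band)
  expect_lt(e_band, e_white)
})

test_that("auto-segmentation and ground-truth boundaries give close features", {
  p <- context_profile("t", 3, 60, inter_element_gap_ms = 80,
                       center_freq_hz = 2500, bandwidth_hz = 1200,
                       tonality = 0.5, pf_drift_hz = 400,
                       dispersion_scale = 0.2)
  for (s in 1:3) {
    rec <- synthesize_call(p, seed = 600 + s)
    f_truth <- extract_features(rec, attr(rec, "elements"))
    f_auto <- extract_features(rec)
    for (v in setdiff(vars10, "pf_jump_hz")) {
      expect_lt(abs(f_auto[[v]] - f_truth[[v]]) / max(abs(f_truth[[v]]), 1e-9),
                0.10)
    }
  }
})
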