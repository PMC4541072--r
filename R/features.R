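#' High-pass filter a recording
#'
#' Removes low-frequency background noise below the lowest call frequency
#' (default cutoff 100 Hz), as routinely applied before spectral analysis.
#' Implemented as a zero-phase 4th-order Butterworth filter (applied forward
#' and backward), giving > 40 dB attenuation one octave below the cutoff and
#' a flat passband.
#'
#' @param recording A `call_recording`.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @return The filtered `call_recording`.
#' @export
highpass_filter <- function(recording, cutoff_hz = 100) {
  fs <- recording$sample_rate_hz
  if (cutoff_hz >= fs / 2)
    stop("cutoff_hz must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "high")
  recording$samples <- as.numeric(
    signal::filtfilt(bf, recording$samples))
  recording
}

#' Downsample a recording to 22.05 kHz
#'
#' Standardises the sampling rate of recordings digitised at higher rates
#' (calls carry no energy above 11 kHz, so only the frequency resolution
#' improves). Inputs already at 22.05 kHz are returned unchanged; upsampling
#' is refused.
#'
#' @param recording A `call_recording` with `sample_rate_hz >= 22050`.
#' @return A `call_recording` at exactly 22050 Hz.
#' @export
resample_to_22k05 <- function(recording) {
  fs <- recording$sample_rate_hz
  if (fs == 22050) return(recording)
  if (fs < 22050)
    stop("refusing to upsample: input rate ", fs, " < 22050 Hz",
         call. = FALSE)
  g <- .gcd(22050L, as.integer(round(fs)))
  recording$samples <- as.numeric(
    signal::resample(recording$samples, 22050L %/% g,
                     as.integer(round(fs)) %/% g))
  recording$sample_rate_hz <- 22050
  recording
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

# smoothed RMS amplitude envelope (5 ms window); the single amplitude
# statistic used for segmentation and main-element determination
smoothed_envelope <- function(x, fs, win_ms = 5) {
  win <- max(round(win_ms / 1000 * fs), 1)
  env <- sqrt(as.numeric(stats::filter(x^2, rep(1 / win, win), sides = 2)))
  env[is.na(env)] <- 0
  env
}

#' Segment a call into elements by amplitude envelope
#'
#' Automated stand-in for manual element labelling: intervals where the
#' smoothed RMS envelope exceeds a threshold relative to the call maximum
#' are taken as elements; gaps shorter than `min_gap_ms` are merged and runs
#' shorter than `min_element_ms` discarded. The main element is the one with
#' the highest envelope peak. External label tracks
#' ([read_label_track()]) take precedence over auto-segmentation wherever
#' both are available.
#'
#' @param recording A (filtered) `call_recording`.
#' @param rel_threshold_db Threshold below the envelope maximum, dB.
#' @param min_element_ms Minimum element duration, ms.
#' @param min_gap_ms Gaps shorter than this are merged, ms.
#' @return An [element_set()].
#' @export
segment_elements <- function(recording, rel_threshold_db = -30,
                             min_element_ms = 5, min_gap_ms = 10) {
  fs <- recording$sample_rate_hz
  x <- recording$samples
  env <- smoothed_envelope(x, fs)
  peak <- max(env)
  if (peak <= 0)
    stop_vocalarm("no elements found: silent recording",
                  "vocalarm_no_elements")
  thr <- peak * 10^(rel_threshold_db / 20)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  if (nrow(iv) == 0)
    stop_vocalarm("no elements found above threshold", "vocalarm_no_elements")
  # merge short gaps
  if (nrow(iv) > 1) {
    keep <- list(iv[1, ])
    for (i in 2:nrow(iv)) {
      gap_ms <- (iv[i, 1] - keep[[length(keep)]][2]) / fs * 1000
      if (gap_ms < min_gap_ms) keep[[length(keep)]][2] <- iv[i, 2]
      else keep[[length(keep) + 1]] <- iv[i, ]
    }
    iv <- do.call(rbind, keep)
  }
  iv <- iv[(iv[, 2] - iv[, 1] + 1) / fs * 1000 >= min_element_ms, ,
           drop = FALSE]
  if (nrow(iv) == 0)
    stop_vocalarm("no elements of sufficient duration",
                  "vocalarm_no_elements")
  peaks <- apply(iv, 1, function(r) max(env[r[1]:r[2]]))
  element_set(cbind(iv[, 1] - 1, iv[, 2]) / fs, main_index = which.max(peaks))
}

#' Short-time spectrogram
#'
#' Magnitude spectrogram with the fixed analysis settings of the pipeline:
#' 1024-point FFT, Hamming window, 64-sample hop (93.75% overlap). Bin
#' spacing is `sample_rate / 1024` (21.5 Hz at 22.05 kHz); the time step is
#' 2.9 ms.
#'
#' @param recording A `call_recording` with at least 1024 samples.
#' @return An object of class `spectrogram`: list with `magnitudes`
#'   (frames x bins, linear), `freq_bins_hz`, `frame_times_s` (frame
#'   centres), `sample_rate_hz`.
#' @export
call_spectrogram <- function(recording) {
  x <- recording$samples
  fs <- recording$sample_rate_hz
  n_fft <- 1024L
  hop <- 64L
  if (length(x) < n_fft)
    stop("recording shorter than one analysis frame (1024 samples)",
         call. = FALSE)
  sg <- signal::specgram(x, n = n_fft, Fs = fs,
                         window = signal::hamming(n_fft),
                         overlap = n_fft - hop)
  mags <- t(Mod(sg$S))                       # frames x bins
  n_frames <- nrow(mags)
  centers <- ((seq_len(n_frames) - 1) * hop + n_fft / 2) / fs
  structure(list(magnitudes = mags,
                 freq_bins_hz = (seq_len(ncol(mags)) - 1) * fs / n_fft,
                 frame_times_s = centers,
                 sample_rate_hz = fs),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, %.1f Hz bins, fs=%g\n",
              nrow(x$magnitudes), ncol(x$magnitudes),
              x$freq_bins_hz[2], x$sample_rate_hz))
  invisible(x)
}

#' Wiener entropy of a magnitude spectrum
#'
#' Ratio of the geometric to the arithmetic mean of the linear magnitudes:
#' 0 for a pure tone (single occupied bin), 1 for a flat (white) spectrum.
#'
#' @param frame_magnitudes Non-negative magnitude vector (one analysis
#'   frame, already restricted to the band of interest).
#' @return Real in \[0, 1\]; `NA` for an all-zero frame.
#' @export
wiener_entropy <- function(frame_magnitudes) {
  m <- frame_magnitudes
  if (!length(m) || all(m <= 0)) return(NA_real_)
  exp(mean(log(m))) / mean(m)
}

#' Spectral quartiles of a magnitude spectrum
#'
#' Frequencies below which 25% and 50% of the cumulative magnitude lie:
#' `q_p` is the lowest bin frequency at which the cumulative magnitude
#' reaches `p` times the total.
#'
#' @param frame_magnitudes Non-negative magnitude vector.
#' @param freqs_hz Bin frequencies (same length).
#' @return Named vector `c(q1_hz, q2_hz)`; `NA`s for a zero-energy frame.
#' @export
spectral_quartiles <- function(frame_magnitudes, freqs_hz) {
  tot <- sum(frame_magnitudes)
  if (tot <= 0) return(c(q1_hz = NA_real_, q2_hz = NA_real_))
  cs <- cumsum(frame_magnitudes)
  c(q1_hz = freqs_hz[which(cs >= 0.25 * tot)[1]],
    q2_hz = freqs_hz[which(cs >= 0.50 * tot)[1]])
}

# indices of frames whose centre falls inside any element interval
frames_in_elements <- function(spec, elements, which_elements = NULL) {
  iv <- elements$intervals
  if (!is.null(which_elements)) iv <- iv[which_elements, , drop = FALSE]
  idx <- lapply(seq_len(nrow(iv)), function(i) {
    which(spec$frame_times_s >= iv[i, 1] & spec$frame_times_s < iv[i, 2])
  })
  idx
}

#' Peak-frequency statistics over the elements of a call
#'
#' Per frame, the peak frequency (PF) is the frequency of the strongest bin
#' at or above 100 Hz. Returns the mean PF over the frames of the main
#' element (and over all element frames), the PF jump (maximal absolute
#' change of PF between successive frames within an element), and the
#' frequency range: the span of frequencies whose mean main-element
#' magnitude exceeds a threshold below the spectral maximum.
#'
#' @param spec A `spectrogram`.
#' @param elements An `element_set`.
#' @param range_threshold_db Threshold for the frequency range, dB below
#'   the maximum of the mean main-element spectrum.
#' @return Named list: `mean_pf_hz` (main element), `mean_pf_all_hz`,
#'   `pf_jump_hz`, `frequency_range_hz`.
#' @export
peak_frequency_stats <- function(spec, elements, range_threshold_db = -24) {
  band <- spec$freq_bins_hz >= 100
  freqs <- spec$freq_bins_hz[band]
  mags <- spec$magnitudes[, band, drop = FALSE]
  per_el <- frames_in_elements(spec, elements)
  if (!length(unlist(per_el)))
    stop("no spectrogram frames fall inside the elements", call. = FALSE)
  pf <- apply(mags, 1, function(m) freqs[which.max(m)])
  main_frames <- per_el[[elements$main_index]]
  jump <- max(c(0, unlist(lapply(per_el, function(ix) {
    if (length(ix) >= 2) abs(diff(pf[ix])) else numeric(0)
  }))))
  mean_spec <- colMeans(mags[main_frames, , drop = FALSE])
  thr <- max(mean_spec) * 10^(range_threshold_db / 20)
  occupied <- freqs[mean_spec > thr]
  list(mean_pf_hz = mean(pf[main_frames]),
       mean_pf_all_hz = mean(pf[unlist(per_el)]),
       pf_jump_hz = jump,
       frequency_range_hz = if (length(occupied)) diff(range(occupied)) else 0)
}

#' Lowest dominant frequency band (FP1)
#'
#' Per frame, FP1 is the lowest-frequency local maximum of the 3-bin
#' smoothed magnitude spectrum exceeding a fraction of the frame maximum.
#' Returns the mean FP1 frequency over the frames of the main element, and
#' the mean relative amplitude at FP1: the smoothed magnitude at FP1 as a
#' fraction of the frame's smoothed maximum, in permille (0-1000), making
#' the measure independent of recording level and frame position.
#'
#' @param spec A `spectrogram`.
#' @param elements An `element_set`.
#' @param min_rel_amp Qualifying threshold as a fraction of the frame
#'   maximum.
#' @param smooth_bins Width of the moving-average smoother (odd).
#' @return Named list `fp1_mean_hz`, `fp1a_mean_relamp` (`NA`s, with a
#'   warning, if no frame has a qualifying peak).
#' @export
dominant_band_fp1 <- function(spec, elements, min_rel_amp = 0.10,
                              smooth_bins = 3) {
  band <- spec$freq_bins_hz >= 100
  freqs <- spec$freq_bins_hz[band]
  mags <- spec$magnitudes[, band, drop = FALSE]
  main_frames <- frames_in_elements(spec, elements)[[elements$main_index]]
  if (!length(main_frames))
    stop("no spectrogram frames fall inside the main element", call. = FALSE)
  kern <- rep(1 / smooth_bins, smooth_bins)
  hits <- vapply(main_frames, function(fi) {
    m <- as.numeric(stats::filter(mags[fi, ], kern, sides = 2))
    m[is.na(m)] <- 0
    n <- length(m)
    if (max(m) <= 0) return(c(NA_real_, NA_real_))
    is_max <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] &
                  m[2:(n - 1)] >= m[3:n], FALSE)
    ok <- which(is_max & m >= min_rel_amp * max(m))
    if (!length(ok)) return(c(NA_real_, NA_real_))
    c(freqs[ok[1]], 1000 * m[ok[1]] / max(m))
  }, numeric(2))
  if (all(is.na(hits[1, ]))) {
    warning("no qualifying FP1 peak in any main-element frame")
    return(list(fp1_mean_hz = NA_real_, fp1a_mean_relamp = NA_real_))
  }
  list(fp1_mean_hz = mean(hits[1, ], na.rm = TRUE),
       fp1a_mean_relamp = mean(hits[2, ], na.rm = TRUE))
}

#' Extract the full feature vector of a call
#'
#' Composes the measurement operations into the per-call vector used by the
#' statistical analyses: temporal features on the compound call (number of
#' elements, mean element duration, call duration), spectral features of the
#' main element (peak frequency, first quartile, PF jump, frequency range,
#' FP1, FP1A), and average characteristics of all elements (Wiener entropy,
#' second quartile, and the all-element mean peak frequency, additionally
#' exported as `mean_pf_all_hz`).
#'
#' @param recording A `call_recording`.
#' @param elements An `element_set`, or `NULL` to auto-segment via
#'   [segment_elements()]. Ground-truth or manual label tracks take
#'   precedence when supplied.
#' @param highpass Apply the 100 Hz high-pass filter first.
#' @param range_threshold_db,fp1_min_rel_amp,fp1_smooth_bins Measurement
#'   thresholds, see [peak_frequency_stats()] and [dominant_band_fp1()].
#' @return One-row data.frame with the ten analysis variables plus
#'   `call_duration_ms`, `mean_pf_all_hz`, and any metadata carried by the
#'   recording.
#' @export
extract_features <- function(recording, elements = NULL, highpass = TRUE,
                             range_threshold_db = -24,
                             fp1_min_rel_amp = 0.10, fp1_smooth_bins = 3) {
  if (recording$sample_rate_hz > 22050)
    recording <- resample_to_22k05(recording)
  if (highpass) recording <- highpass_filter(recording, 100)
  if (is.null(elements)) elements <- segment_elements(recording)
  spec <- call_spectrogram(recording)
  band <- spec$freq_bins_hz >= 100
  freqs <- spec$freq_bins_hz[band]
  mags <- spec$magnitudes[, band, drop = FALSE]

  per_el <- frames_in_elements(spec, elements)
  all_frames <- unlist(per_el)
  main_frames <- per_el[[elements$main_index]]
  if (!length(all_frames) || !length(main_frames))
    stop_vocalarm("elements contain no complete analysis frames",
                  "vocalarm_no_elements")

  ent <- vapply(all_frames, function(i) wiener_entropy(mags[i, ]),
                numeric(1))
  q_all <- vapply(all_frames, function(i)
    spectral_quartiles(mags[i, ], freqs), numeric(2))
  q_main <- vapply(main_frames, function(i)
    spectral_quartiles(mags[i, ], freqs), numeric(2))
  pf <- peak_frequency_stats(spec, elements, range_threshold_db)
  fp1 <- dominant_band_fp1(spec, elements, fp1_min_rel_amp, fp1_smooth_bins)

  iv <- elements$intervals
  out <- data.frame(
    n_elements = nrow(iv),
    element_duration_ms = mean(iv[, 2] - iv[, 1]) * 1000,
    wiener_entropy = mean(ent, na.rm = TRUE),
    peak_frequency_hz = pf$mean_pf_hz,
    first_quartile_hz = mean(q_main[1, ], na.rm = TRUE),
    second_quartile_hz = mean(q_all[2, ], na.rm = TRUE),
    pf_jump_hz = pf$pf_jump_hz,
    frequency_range_hz = pf$frequency_range_hz,
    fp1_mean_hz = fp1$fp1_mean_hz,
    fp1a_mean_relamp = fp1$fp1a_mean_relamp,
    call_duration_ms = (iv[nrow(iv), 2] - iv[1, 1]) * 1000,
    mean_pf_all_hz = pf$mean_pf_all_hz)
  meta <- data.frame(caller_id = recording$caller_id, sex = recording$sex,
                     population = recording$population,
                     context = recording$context,
                     bout_id = recording$bout_id, stringsAsFactors = FALSE)
  cbind(meta, out)
}

#' Extract a feature table from a batch of recordings
#'
#' Applies [extract_features()] to each recording, using ground-truth
#' element boundaries when present (attribute `"elements"`, e.g. from
#' [synthesize_call()]) unless `use_truth = FALSE`.
#'
#' @param recordings List of `call_recording`s.
#' @param use_truth Use attached ground-truth element boundaries when
#'   available.
#' @param ... Passed to [extract_features()].
#' @return Feature table (data.frame) with one row per call.
#' @export
extract_feature_table <- function(recordings, use_truth = TRUE, ...) {
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    el <- if (use_truth) attr(rec, "elements") else NULL
    cbind(call_id = sprintf("call%04d", i),
          extract_features(rec, elements = el, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
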