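#' Context profile for waveform synthesis
#'
#' Parameter set describing the calls of one eliciting context: how many
#' elements a call has, how long they are, how they are spaced, and the
#' spectral character of each element (centre frequency, bandwidth, tonality,
#' frame-to-frame peak-frequency drift).
#'
#' `tonality` in \[0, 1\] sets the mix between a tonal component and
#' band-limited noise; it parameterises the expected spectral flatness of an
#' element as `1 - tonality`, so a profile built from a measured Wiener
#' entropy `h` uses `tonality = 1 - h`. Internally the generator solves for
#' the broadband noise-floor level that makes the idealised magnitude
#' spectrum of the element attain that flatness over the analysis band.
#'
#' @param context Context label.
#' @param n_elements_mean Mean number of elements per call (>= 1).
#' @param element_duration_ms Mean element duration, ms.
#' @param inter_element_gap_ms Mean silent gap between elements, ms.
#' @param center_freq_hz Spectral centre (maps to peak frequency), Hz.
#' @param bandwidth_hz Width of the noise band around the centre, Hz.
#' @param tonality Real in \[0, 1\]; 1 = pure tone.
#' @param pf_drift_hz Peak-to-peak range of the within-element peak-frequency
#'   drift (controls the PF jump feature), Hz.
#' @param dispersion_scale Non-negative multiplier on all between-call
#'   jitter (element counts, durations, gaps, amplitudes); 0 gives
#'   deterministic construction.
#' @return An object of class `context_profile`.
#' @export
context_profile <- function(context, n_elements_mean, element_duration_ms,
                            inter_element_gap_ms = 50,
                            center_freq_hz, bandwidth_hz, tonality,
                            pf_drift_hz = 0, dispersion_scale = 1) {
  stopifnot(n_elements_mean >= 1, element_duration_ms > 0,
            inter_element_gap_ms > 0, center_freq_hz > 0, bandwidth_hz > 0,
            tonality >= 0, tonality <= 1, pf_drift_hz >= 0,
            dispersion_scale >= 0)
  structure(list(context = as.character(context),
                 n_elements_mean = n_elements_mean,
                 element_duration_ms = element_duration_ms,
                 inter_element_gap_ms = inter_element_gap_ms,
                 center_freq_hz = center_freq_hz,
                 bandwidth_hz = bandwidth_hz,
                 tonality = tonality,
                 pf_drift_hz = pf_drift_hz,
                 dispersion_scale = dispersion_scale),
            class = "context_profile")
}

# noise-floor level r solving  r^(1-f) / (f + (1-f) r) = h  on the analysis
# band, where f is the fraction of the band occupied by the element's noise
# band and h = 1 - tonality is the target spectral flatness
solve_noise_floor <- function(flatness, band_fraction) {
  h <- min(max(flatness, 0), 0.999)
  f <- band_fraction
  if (f >= 0.999 || h <= 0) return(if (h <= 0) 0 else 1)
  g <- function(r) r^(1 - f) / (f + (1 - f) * r) - h
  if (g(1) < 0) return(1)
  stats::uniroot(g, c(1e-12, 1), tol = 1e-10)$root
}

# one element: spectrally shaped noise (unit band, floor r elsewhere in the
# analysis band) mixed with a phase-continuous drifting tone, raised-cosine
# 5 ms on/off ramps
synth_element <- function(n_samp, fs, profile, ramp_ms = 5) {
  nyq <- fs / 2
  band_hi_lim <- 0.98 * nyq
  f_lo <- max(100, profile$center_freq_hz - profile$bandwidth_hz / 2)
  f_hi <- min(profile$center_freq_hz + profile$bandwidth_hz / 2, band_hi_lim)
  frac_in <- (f_hi - f_lo) / (band_hi_lim - 100)
  # the idealized solve targets the expected magnitude spectrum; realized
  # STFT spectra sit lower (Rayleigh geometric-mean penalty of noise bins
  # plus the tone's share of the arithmetic mean), so the flatness target
  # is inflated by a fixed calibration constant
  r <- solve_noise_floor((1 - profile$tonality) * 1.26, frac_in)

  # frequency-domain shaping of white noise
  freqs <- (seq_len(n_samp) - 1) / n_samp * fs
  half <- freqs > nyq
  freqs[half] <- fs - freqs[half]
  shape <- numeric(n_samp)
  shape[freqs >= 100 & freqs <= band_hi_lim] <- r
  shape[freqs >= f_lo & freqs <= f_hi] <- 1
  noise <- Re(fft(fft(rnorm(n_samp)) * shape, inverse = TRUE)) / n_samp
  rms <- sqrt(mean(noise^2))
  if (rms > 0) noise <- noise / rms

  # drifting tone: piecewise-constant frequency per ~512-sample segment,
  # uniform in center +/- drift/2, phase accumulated across segments
  seg <- 512L
  n_seg <- ceiling(n_samp / seg)
  off <- if (profile$pf_drift_hz > 0 && n_seg > 1)
    runif(n_seg, -profile$pf_drift_hz / 2, profile$pf_drift_hz / 2)
  else rep(0, n_seg)
  # centre the drift within the element so the mean instantaneous frequency
  # equals center_freq_hz by construction (the profile's centre is defined
  # as the mean peak frequency); frequency differences are unaffected
  off <- off - mean(off)
  fseg <- pmin(pmax(profile$center_freq_hz + off, 100), band_hi_lim)
  finst <- rep(fseg, each = seg)[seq_len(n_samp)]
  phase <- 2 * pi * cumsum(finst) / fs
  tone <- sqrt(2) * sin(phase)

  x <- profile$tonality * tone + (1 - profile$tonality) * noise
  n_ramp <- min(round(ramp_ms / 1000 * fs), floor(n_samp / 2))
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[n_samp - n_ramp + seq_len(n_ramp)] <-
      x[n_samp - n_ramp + seq_len(n_ramp)] * rev(ramp)
  }
  x
}

#' Synthesize a multi-element call waveform
#'
#' Generates a call as a sequence of band-limited noise/tone bursts separated
#' by silent gaps, following a [context_profile()]. Ground-truth element
#' boundaries are attached as attribute `"elements"` (an [element_set()]),
#' so segmentation and feature recovery can be validated against
#' construction truth.
#'
#' @param profile A `context_profile`.
#' @param sample_rate_hz Sampling rate; must be at least twice the top of
#'   the profile's frequency band.
#' @param seed Optional integer seed (fixing it fixes the waveform
#'   bit-for-bit).
#' @param ... Metadata fields passed to [call_recording()].
#' @return A `call_recording` with attributes `"elements"` (ground truth)
#'   and `"profile"`.
#' @export
synthesize_call <- function(profile, sample_rate_hz = 22050, seed = NULL,
                            ...) {
  stopifnot(inherits(profile, "context_profile"))
  top <- profile$center_freq_hz + profile$bandwidth_hz / 2
  if (sample_rate_hz < 2 * top)
    stop("sample_rate_hz (", sample_rate_hz,
         ") below twice the profile's top frequency (", 2 * top, " Hz)",
         call. = FALSE)
  local_seed(seed)
  fs <- sample_rate_hz
  disp <- profile$dispersion_scale

  n_el <- if (disp == 0) max(1L, as.integer(round(profile$n_elements_mean)))
  else max(1L, as.integer(round(rnorm(1, profile$n_elements_mean,
                                      disp * sqrt(profile$n_elements_mean) / 2))))
  dur_ms <- profile$element_duration_ms * exp(rnorm(n_el, 0, 0.10 * disp))
  gap_ms <- profile$inter_element_gap_ms * exp(rnorm(max(n_el - 1, 0), 0,
                                                     0.15 * disp))
  amp <- exp(rnorm(n_el, 0, 0.15 * disp))

  pad <- round(0.030 * fs)                     # 30 ms silent margins
  pieces <- vector("list", 2 * n_el)
  starts <- numeric(n_el)
  pos <- pad
  for (i in seq_len(n_el)) {
    n_samp <- max(round(dur_ms[i] / 1000 * fs), 32L)
    pieces[[2 * i - 1]] <- amp[i] * synth_element(n_samp, fs, profile)
    starts[i] <- pos
    pos <- pos + n_samp
    if (i < n_el) {
      n_gap <- max(round(gap_ms[i] / 1000 * fs), 1L)
      pieces[[2 * i]] <- numeric(n_gap)
      pos <- pos + n_gap
    }
  }
  samples <- c(numeric(pad), unlist(pieces), numeric(pad))
  peak <- max(abs(samples))
  if (peak > 0) samples <- samples * (0.9 / peak)

  ends <- starts + round(pmax(dur_ms / 1000 * fs, 32L))
  # main element = highest realized amplitude (the field definition), judged
  # on the same smoothed envelope the segmenter uses; under noise draws this
  # need not be the element with the largest synthesis gain
  env <- smoothed_envelope(samples, fs)
  peaks <- vapply(seq_len(n_el), function(i)
    max(env[(starts[i] + 1):ends[i]]), numeric(1))
  truth <- element_set(cbind(starts, ends) / fs,
                       main_index = which.max(peaks))
  rec <- call_recording(samples, fs, context = profile$context, ...)
  attr(rec, "elements") <- truth
  attr(rec, "profile") <- profile
  rec
}

#' Waveform-level context profiles from the reference tables
#'
#' Builds one [context_profile()] per context from the built-in descriptive
#' statistics ([vervet_descriptives()]): element count and duration are taken
#' directly; centre frequency = the context's mean peak frequency; bandwidth
#' = twice the interquartile spread (Q2 - Q1); tonality = 1 - mean Wiener
#' entropy; PF drift = the mean PF jump. The inter-element gap (50 ms) is a
#' fixed package choice.
#'
#' @inheritParams vervet_descriptives
#' @param dispersion_scale Passed to each profile.
#' @return Named list of `context_profile` objects.
#' @export
waveform_profiles <- function(sex = c("female", "male"),
                              dispersion_scale = 1) {
  d <- vervet_descriptives(sex)
  get <- function(v, ctx) d$mean[d$variable == v & d$context == ctx]
  contexts <- unique(d$context)
  profs <- lapply(contexts, function(ctx) {
    context_profile(
      context = ctx,
      n_elements_mean = get("n_elements", ctx),
      element_duration_ms = get("element_duration_ms", ctx),
      inter_element_gap_ms = 50,
      center_freq_hz = get("peak_frequency_hz", ctx),
      bandwidth_hz = max(2 * (get("second_quartile_hz", ctx) -
                                get("first_quartile_hz", ctx)), 200),
      tonality = 1 - get("wiener_entropy", ctx),
      pf_drift_hz = get("pf_jump_hz", ctx),
      dispersion_scale = dispersion_scale)
  })
  names(profs) <- contexts
  profs
}

#' Synthesize a batch of calls across contexts
#'
#' @param profiles Named list of `context_profile`s (e.g.
#'   [waveform_profiles()]).
#' @param n_per_context Calls per context.
#' @param sample_rate_hz Sampling rate.
#' @param seed Integer seed for the whole batch.
#' @return List of `call_recording`s, each with ground-truth `"elements"`.
#' @export
synthesize_calls <- function(profiles, n_per_context, sample_rate_hz = 22050,
                             seed = NULL) {
  local_seed(seed)
  out <- list()
  for (p in profiles) {
    for (i in seq_len(n_per_context)) {
      rec <- synthesize_call(p, sample_rate_hz,
                             caller_id = sprintf("%s_%02d", p$context, i),
                             bout_id = sprintf("%s_%02d_b1", p$context, i))
      out[[length(out) + 1]] <- rec
    }
  }
  out
}

#' Population specification for feature-level synthesis
#'
#' Describes a synthetic study population at the level of the extracted
#' feature table: per-context mean/SD profiles for the ten analysis
#' variables, the number of individuals per context, calls per individual,
#' and the scale of per-individual random intercepts.
#'
#' @param profiles List of feature profiles as returned by
#'   [feature_profiles()]: each a list with `context`, `mean` (named
#'   10-vector) and `sd` (named 10-vector of per-call SDs).
#' @param n_individuals_per_context,calls_per_individual Counts (>= 1).
#' @param individual_sd Scalar or named per-variable vector of random
#'   intercept scales, expressed as multipliers of each variable's per-call
#'   SD (0 = no individual effect).
#' @param dispersion Multiplier on the per-call residual SDs (0 gives
#'   degenerate draws at the context means).
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(profiles, n_individuals_per_context,
                            calls_per_individual, individual_sd = 0,
                            dispersion = 1, seed = NULL) {
  if (n_individuals_per_context < 1 || calls_per_individual < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (any(individual_sd < 0) || dispersion < 0)
    stop("scales must be non-negative", call. = FALSE)
  structure(list(profiles = profiles,
                 n_individuals_per_context = as.integer(n_individuals_per_context),
                 calls_per_individual = as.integer(calls_per_individual),
                 individual_sd = individual_sd, dispersion = dispersion,
                 seed = seed),
            class = "population_spec")
}

#' Feature-level context profiles from the reference tables
#'
#' Converts the built-in per-context means and SEMs into generator profiles,
#' deriving per-call SDs as `sem * sqrt(n)` with the per-context call counts
#' of the study sample ([vervet_context_n()]).
#'
#' @inheritParams vervet_descriptives
#' @return Named list of profiles (`context`, `mean`, `sd`).
#' @export
feature_profiles <- function(sex = c("female", "male")) {
  d <- vervet_descriptives(sex)
  contexts <- unique(d$context)
  profs <- lapply(contexts, function(ctx) {
    rows <- d[d$context == ctx, ]
    list(context = ctx,
         mean = setNames(rows$mean, rows$variable),
         sd = setNames(rows$sem * sqrt(rows$n), rows$variable))
  })
  names(profs) <- contexts
  profs
}

# mean of a normal(mu, sd) truncated to [lo, hi]
.trunc_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-12) return(if (mu < lo) lo else hi)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# pre-truncation location whose truncated mean equals `target`, so that the
# generated sample means match the reference table means despite truncation
.trunc_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  f <- function(mu) .trunc_mean(mu, sd, lo, hi) - target
  stats::uniroot(f, c(target - 8 * sd, target + 8 * sd), tol = 1e-9,
                 extendInt = "upX")$root
}

# one truncated-normal draw block: redraw values outside [lo, hi]
rtruncnorm_block <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  mean <- .trunc_location(mean, sd, lo, hi)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0
  while (length(bad) && guard < 1000) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1
  }
  if (length(bad)) x[bad] <- min(max(mean, lo), hi)
  x
}

#' Synthesize a feature table
#'
#' Draws per-call feature vectors emulating the per-context distributions of
#' the reference descriptive statistics: each variable is drawn independently
#' from a normal distribution truncated at 0 (Wiener entropy additionally at
#' 1), with an additive per-individual random intercept on each variable.
#' Ground truth (the generating spec) is attached as attribute `"truth"`.
#'
#' @param spec A [population_spec()].
#' @return A data.frame feature table with metadata columns (`call_id`,
#'   `caller_id`, `context`, `bout_id`) and the ten analysis variables.
#' @export
synthesize_feature_table <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  local_seed(spec$seed)
  vars <- call_feature_vars()
  ind_sd <- spec$individual_sd
  if (length(ind_sd) == 1) ind_sd <- setNames(rep(ind_sd, length(vars)), vars)
  rows <- list()
  for (p in spec$profiles) {
    pv <- names(p$mean)
    for (i in seq_len(spec$n_individuals_per_context)) {
      caller <- sprintf("%s_id%02d", p$context, i)
      icpt <- rnorm(length(pv), 0, unname(ind_sd[pv] * p$sd[pv]))
      vals <- vapply(seq_along(pv), function(v) {
        hi <- if (pv[v] == "wiener_entropy") 1 else Inf
        rtruncnorm_block(spec$calls_per_individual,
                         p$mean[v] + icpt[v], spec$dispersion * p$sd[v],
                         0, hi)
      }, numeric(spec$calls_per_individual))
      vals <- matrix(vals, nrow = spec$calls_per_individual,
                     dimnames = list(NULL, pv))
      d <- data.frame(caller_id = caller, context = p$context,
                      bout_id = paste0(caller, "_b1"),
                      stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- cbind(d, as.data.frame(vals))
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(call_id = sprintf("call%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  attr(out, "truth") <- spec
  out
}
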