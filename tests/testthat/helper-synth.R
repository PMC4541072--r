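# Shared fixtures, all built in code.

vars10 <- call_feature_vars()

# base feature-level profile: realistic scales, entropy safely inside (0, 1)
base_mean <- c(4, 40, 0.5, 1000, 900, 1800, 500, 3000, 900, 500)
base_sd   <- c(1, 5, 0.05, 100, 80, 150, 80, 300, 80, 50)

# four mutually equidistant contexts: context i shifts its own pair of
# variables by `sep` within-SDs (entropy, variable 3, is never shifted)
blob_profiles <- function(sep = 6, k = 4) {
  pairs <- list(c(1, 2), c(4, 5), c(6, 7), c(8, 9))
  lapply(seq_len(k), function(i) {
    shift <- numeric(10)
    shift[pairs[[i]]] <- sep
    list(context = LETTERS[i],
         mean = setNames(base_mean + shift * base_sd, vars10),
         sd = setNames(base_sd, vars10))
  })
}

single_profile <- function(context = "A") {
  list(context = context, mean = setNames(base_mean, vars10),
       sd = setNames(base_sd, vars10))
}

# pure-tone recording
tone_recording <- function(freq_hz, dur_s = 0.2, fs = 22050, amp = 0.8) {
  call_recording(amp * sin(2 * pi * freq_hz * (0:(round(dur_s * fs) - 1)) / fs),
                 fs)
}

# noise with an exactly band-limited spectrum (FFT shaping); optional
# broadband floor (relative amplitude) emulating a recording noise floor
shaped_noise_recording <- function(f_lo, f_hi, dur_s = 0.3, fs = 22050,
                                   seed = 1, floor_rel = 0) {
  withr::with_seed(seed, {
    n <- round(dur_s * fs)
    freqs <- (seq_len(n) - 1) / n * fs
    freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]
    shape <- pmax(as.numeric(freqs >= f_lo & freqs <= f_hi), floor_rel)
    x <- Re(fft(fft(rnorm(n)) * shape, inverse = TRUE)) / n
    call_recording(0.8 * x / max(abs(x)), fs)
  })
}

# nested pDFA simulation table: n_ctx contexts x n_ind individuals x
# n_calls calls on 4 variables; individual random intercepts of scale
# ind_sd; context effect = `effect` residual-SDs along a single axis
pdfa_sim_table <- function(seed, ind_sd = 2, effect = 0, n_ctx = 3,
                           n_ind = 5, n_calls = 4) {
  vars <- vars10[4:7]
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_ctx), function(ci) {
      do.call(rbind, lapply(seq_len(n_ind), function(i) {
        icpt <- rnorm(4, 0, ind_sd)
        mu <- icpt + c(effect * (ci - 1), 0, 0, 0)
        v <- matrix(rnorm(4 * n_calls, rep(mu, each = n_calls), 1),
                    n_calls, 4, dimnames = list(NULL, vars))
        cbind(data.frame(caller_id = sprintf("c%d_i%d", ci, i),
                         context = paste0("ctx", ci),
                         stringsAsFactors = FALSE),
              as.data.frame(v))
      }))
    })
    do.call(rbind, rows)
  })
}

# do two label vectors describe the same partition?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
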