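#' Call recording object
#'
#' Container for a single mono call waveform with its metadata: caller
#' identity, sex, population, eliciting context, and calling bout.
#'
#' @param samples Numeric amplitude vector in \[-1, 1\].
#' @param sample_rate_hz Sampling rate in Hz.
#' @param caller_id,sex,population,context,bout_id Per-call metadata.
#' @return An object of class `call_recording`.
#' @export
call_recording <- function(samples, sample_rate_hz, caller_id = NA_character_,
                           sex = NA_character_, population = NA_character_,
                           context = NA_character_, bout_id = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate_hz > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 caller_id = caller_id, sex = sex, population = population,
                 context = context, bout_id = bout_id),
            class = "call_recording")
}

#' @export
print.call_recording <- function(x, ...) {
  cat(sprintf("<call_recording> %.3f s @ %g Hz",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz))
  if (!is.na(x$context)) cat(sprintf(" | context=%s", x$context))
  if (!is.na(x$caller_id)) cat(sprintf(" caller=%s", x$caller_id))
  cat("\n")
  invisible(x)
}

#' Element interval set
#'
#' Ordered, non-overlapping time intervals (seconds, half-open) delimiting
#' the elements of a multi-element call, with the index of the main element
#' (the element with the highest amplitude).
#'
#' @param intervals Two-column matrix of `(start_s, end_s)` rows.
#' @param main_index Row index of the main element.
#' @return An object of class `element_set`.
#' @export
element_set <- function(intervals, main_index = 1L) {
  intervals <- matrix(as.numeric(intervals), ncol = 2,
                      dimnames = list(NULL, c("start_s", "end_s")))
  if (nrow(intervals) == 0)
    stop_vocalarm("element set must contain at least one interval",
                  "vocalarm_no_elements")
  if (any(intervals[, 2] <= intervals[, 1]))
    stop("element intervals must have end > start", call. = FALSE)
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
    stop("element intervals must be non-overlapping and increasing",
         call. = FALSE)
  main_index <- as.integer(main_index)
  if (main_index < 1 || main_index > nrow(intervals))
    stop("main_index out of range", call. = FALSE)
  structure(list(intervals = intervals, main_index = main_index),
            class = "element_set")
}

#' @export
print.element_set <- function(x, ...) {
  cat(sprintf("<element_set> %d element(s), main = %d\n",
              nrow(x$intervals), x$main_index))
  invisible(x)
}
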