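#' The ten analysis variables
#'
#' Column names of the acoustic variables used in clustering and discriminant
#' analyses, in their fixed export order: number of elements, mean element
#' duration, Wiener entropy, peak frequency, first and second spectral
#' quartiles, maximal peak-frequency jump, frequency range, and the frequency
#' and relative amplitude of the lowest dominant frequency band (FP1).
#'
#' @return Character vector of length 10.
#' @export
call_feature_vars <- function() {
  c("n_elements", "element_duration_ms", "wiener_entropy",
    "peak_frequency_hz", "first_quartile_hz", "second_quartile_hz",
    "pf_jump_hz", "frequency_range_hz", "fp1_mean_hz", "fp1a_mean_relamp")
}

# metadata columns recognised in feature tables
.meta_vars <- c("call_id", "caller_id", "sex", "population", "context", "bout_id")

# round half away from zero, as classification tables are conventionally printed
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# set the RNG locally for the calling frame; NULL leaves the stream untouched
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}

stop_vocalarm <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "vocalarm_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# pull the feature-variable matrix out of a feature table
feature_matrix <- function(table, variables = NULL) {
  variables <- variables %||% intersect(call_feature_vars(), names(table))
  missing <- setdiff(variables, names(table))
  if (length(missing))
    stop("feature table lacks variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(table[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
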