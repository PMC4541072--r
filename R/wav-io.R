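#' Read and write mono PCM WAV files
#'
#' Minimal RIFF/WAVE I/O for 16-bit mono recordings, the format of digitised
#' field recordings handled by the pipeline. Samples are stored in the file as
#' signed 16-bit integers and exposed in R as doubles in \[-1, 1\].
#'
#' @param recording A `call_recording` (see [synthesize_call()]) or a list
#'   with elements `samples` and `sample_rate_hz`.
#' @param path File path.
#' @return `read_wav()` returns a `call_recording`; `write_wav()` returns
#'   `path` invisibly.
#' @export
write_wav <- function(recording, path) {
  x <- recording$samples
  fs <- as.integer(recording$sample_rate_hz)
  stopifnot(length(x) > 0, fs > 0)
  pcm <- as.integer(pmax(-1, pmin(1, x)) * 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), n = 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), n = 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = size %/% 2, size = 2,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(fs) || is.null(samples))
    stop("malformed WAV file: ", path, call. = FALSE)
  if (!identical(channels, 1L) || !identical(bits, 16L))
    stop("only 16-bit mono WAV supported", call. = FALSE)
  call_recording(samples / 32767, fs)
}

#' Read and write element label tracks
#'
#' Tab-separated label tracks (columns `start_s`, `end_s`, `label`), the
#' dialect used by spectrogram labelling software, giving the start and end
#' points of call elements. `read_label_track()` returns an [element_set()];
#' the main element is taken from a label equal to `"main"` when present,
#' otherwise the longest element.
#'
#' @param elements An `element_set`.
#' @param path File path.
#' @return `read_label_track()` returns an `element_set`.
#' @export
write_label_track <- function(elements, path) {
  d <- data.frame(start_s = elements$intervals[, 1],
                  end_s = elements$intervals[, 2],
                  label = ifelse(seq_len(nrow(elements$intervals)) ==
                                   elements$main_index, "main", "element"))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_track
#' @export
read_label_track <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("start_s", "end_s") %in% names(d)))
  main <- if ("label" %in% names(d) && any(d$label == "main"))
    which(d$label == "main")[1] else which.max(d$end_s - d$start_s)
  element_set(cbind(d$start_s, d$end_s), main_index = main)
}
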