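#' Audio clip container
#'
#' Uncalibrated single-channel audio: dimensionless amplitudes in `[-1, 1]`.
#' Ear-canal recordings in this workflow are uncalibrated, so clip levels are
#' relative dB only, never absolute SPL.
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz (>= 2000).
#' @param label one of `"PT"`, `"NO_PT"` or a free label.
#' @return object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, label = "PT") {
  if (!all(is.finite(samples))) stop("audio_clip: non-finite samples", call. = FALSE)
  if (sample_rate < 2000) stop("audio_clip: sample_rate must be >= 2000 Hz", call. = FALSE)
  if (max(abs(samples), 0) > 1 + 1e-9) {
    stop("audio_clip: samples must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 label = label),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.2f s @ %d Hz (%d samples)\n", x$label,
              length(x$samples) / x$sample_rate, as.integer(x$sample_rate),
              length(x$samples)))
  invisible(x)
}

#' Write an audio clip as 16-bit PCM WAV
#'
#' @param clip an [audio_clip()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(pmax(clip$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(clip$sample_rate)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Reads mono (or the first channel of multi-channel) 16-bit PCM WAV.
#'
#' @param path WAV file path.
#' @param label label for the returned clip.
#' @return an [audio_clip()].
#' @export
read_wav <- function(path, label = "PT") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file", call. = FALSE)
  fs <- NULL; nchan <- 1L; bits <- 16L; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      nchan <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      if (bits != 16) stop("read_wav: only 16-bit PCM supported", call. = FALSE)
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
      if (nchan > 1) pcm <- pcm[seq(1, length(pcm), by = nchan)]
      samples <- pcm / 32767
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(fs) || is.null(samples)) stop("read_wav: malformed WAV", call. = FALSE)
  audio_clip(pmin(pmax(samples, -1), 1), fs, label = label)
}
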