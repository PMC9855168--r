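# Minimal RIFF/WAVE PCM I/O. Autonomous recorders (AudioMoth, Song Meter)
# produce plain PCM WAV; only that subset is supported.

#' Write a mono PCM WAV file
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped. Output is
#' 16-bit little-endian PCM, the format produced by the autonomous recorders
#' this package emulates.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param path Output file path.
#' @param rate Sample rate in Hz (default 48000).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate = 48000) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a nonempty numeric vector", call. = FALSE)
  rate <- as.integer(rate)
  n <- length(samples)
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")    # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Supports uncompressed 8-, 16- and 24-bit mono PCM. Stereo files are
#' rejected: down-mix to mono before feature extraction, since the band
#' energies of a single channel are what the detector was designed for.
#'
#' @param path WAV file path.
#' @return A list with `samples` (numeric in `[-1, 1]`), `rate` (Hz) and
#'   `bit` (bits per sample).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  rate <- NULL; bit <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only uncompressed PCM WAV is supported", call. = FALSE)
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))  # block align
      bit <- readBin(con, "integer", 1, size = 2, endian = "little")
      seek(con, size - 16L, origin = "current")
    } else if (identical(id, "data")) {
      if (is.null(bit)) stop("malformed WAV: data before fmt chunk", call. = FALSE)
      if (channels != 1L)
        stop("stereo WAV not supported: down-mix to mono first ",
             "(e.g. average the two channels)", call. = FALSE)
      if (bit == 16L) {
        samples <- readBin(con, "integer", size / 2L, size = 2,
                           endian = "little", signed = TRUE) / 32768
      } else if (bit == 8L) {
        samples <- (readBin(con, "integer", size, size = 1,
                            endian = "little", signed = FALSE) - 128) / 128
      } else if (bit == 24L) {
        raw3 <- readBin(con, "raw", size)
        m <- matrix(as.integer(raw3), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else stop("unsupported bit depth: ", bit, call. = FALSE)
      break
    } else {
      seek(con, size + (size %% 2L), origin = "current")
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  list(samples = samples, rate = rate, bit = bit)
}
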