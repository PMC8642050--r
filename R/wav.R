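# Minimal RIFF/WAVE I/O: mono, 16-bit PCM or 32-bit IEEE float.

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE-float mono files. Samples are returned
#' on the +/- 1.0 full scale.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("read_wav: no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate         = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("read_wav: only mono files are supported")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        s <- readBin(con, "integer", n, size = 2, signed = TRUE,
                     endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        s <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop("read_wav: unsupported format (need 16-bit PCM or 32-bit float)")
      }
      return(audio_signal(s, fmt$rate))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
}

#' Write a mono WAV file
#'
#' @param x an [audio_signal()]; samples outside +/- 1 are clipped for PCM.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16L) {
  stopifnot(inherits(x, "audio_signal"), bits %in% c(16L, 32L))
  n <- length(x$samples)
  bytes_per <- bits %/% 8L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt_code <- if (bits == 16L) 1L else 3L
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(round(x$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(x$rate) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (bits == 16L) {
    s <- pmin(pmax(x$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(s * 32768)), con, size = 2, endian = "little")
  } else {
    writeBin(x$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
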