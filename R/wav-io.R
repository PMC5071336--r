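#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the recording formats used for mouse USV work:
#' uncompressed PCM (16-bit integer) or IEEE float (32-bit), single channel.
#' Stereo files are rejected: USV sessions here are single-microphone.
#'
#' @param path path to a .wav file.
#' @return A list with elements \code{wave} (numeric vector scaled to
#'   [-1, 1] for PCM) and \code{rate} (samples per second).
#' @seealso \code{\link{writeWav}}
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1L, size = 2L,
                              endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1L, size = 2L,
                           endian = "little", signed = FALSE),
        rate = readBin(raw[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, size = 2L,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1L)
        stop("only mono WAV files are supported (found ", fmt$channels,
             " channels): ", path)
      if (fmt$audioFormat == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        x <- readBin(con, "integer", n, size = 2L, endian = "little",
                     signed = TRUE) / 32768
      } else if (fmt$audioFormat == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        x <- readBin(con, "double", n, size = 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audioFormat, ", ",
             fmt$bits, " bits): only 16-bit PCM and 32-bit float are read")
      }
      return(list(wave = x, rate = fmt$rate))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
}

#' Write a mono WAV file
#'
#' @param wave numeric vector in [-1, 1].
#' @param rate sampling rate (Hz).
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(wave, rate, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave)
  bytesPerSample <- bits %/% 8L
  dataSize <- n * bytesPerSample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * bytesPerSample), con, size = 4L,
           endian = "little")
  writeBin(as.integer(bytesPerSample), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  if (bits == 16L) {
    x <- as.integer(pmax(-32768, pmin(32767, round(wave * 32768))))
    writeBin(x, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(wave), con, size = 4L, endian = "little")
  }
  invisible(path)
}
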