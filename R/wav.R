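#' Read a WAV file into an audio track
#'
#' Minimal RIFF/WAVE reader supporting 16- and 24-bit integer PCM and
#' 32-bit IEEE float, mono or multichannel (channels are averaged to
#' mono, matching the diotic stimulus presentation).
#'
#' @param path path to a `.wav` file.
#' @return an [audio_track()], samples scaled to `[-1, 1]` for PCM.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate         = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt or data chunk")
  bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% bytes
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n, 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop(sprintf("unsupported WAV format (format %d, %d bits)",
                 fmt$audio_format, fmt$bits))
  }
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_track(x, fmt$rate)
}

#' Write an audio track to a WAV file
#'
#' @param track an [audio_track()].
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @export
write_wav <- function(track, path, bits = 16L) {
  stopifnot(inherits(track, "audio_track"), bits %in% c(16L, 32L))
  x <- track$samples
  bytes <- bits %/% 8
  data_size <- length(x) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 16L) 1L else 3L, 1L), con, 2, endian = "little")
  writeBin(as.integer(track$rate), con, 4, endian = "little")
  writeBin(as.integer(track$rate * bytes), con, 4, endian = "little")
  writeBin(c(as.integer(bytes), as.integer(bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con, 2,
             endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
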