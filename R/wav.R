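#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats used for speech stimuli:
#' 16- or 24-bit integer PCM and 32-bit IEEE float, single channel (the
#' first channel of multi-channel files is taken).  Integer samples are
#' scaled to \[-1, 1).
#'
#' @param path file path.
#' @return an [audio_buffer()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt or data chunk: ", path)
  nc <- fmt$n_channels
  x <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3) {
        readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
      } else stop("32-bit integer PCM is not supported")
    },
    stop("unsupported bit depth: ", fmt$bits))
  if (nc > 1L) x <- x[seq(1, length(x), by = nc)]
  audio_buffer(x, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param x an [audio_buffer()].
#' @param path output path.
#' @param bits 16 or 24 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16L) {
  if (!bits %in% c(16L, 24L, 32L)) stop("bits must be 16, 24 or 32")
  s <- x$samples
  fs <- as.integer(x$sample_rate_hz)
  fmt_code <- if (bits == 32L) 3L else 1L
  bytes_per <- bits / 8L
  data_size <- length(s) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    v <- as.integer(pmax(pmin(round(s * 32768), 32767), -32768))
    writeBin(v, con, 2, endian = "little")
  } else if (bits == 24L) {
    v <- pmax(pmin(round(s * 8388608), 8388607), -8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  } else {
    writeBin(s, con, 4, endian = "little")
  }
  invisible(path)
}
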