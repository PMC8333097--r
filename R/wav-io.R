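#' Read a mono RIFF WAV file
#'
#' Supports the two encodings this package writes: 16-bit integer PCM
#' (format code 1) and 32-bit IEEE float (format code 3). Samples are
#' returned as doubles in `[-1, 1]`. Multi-channel files are rejected:
#' the classification pipeline is defined on single-channel recordings.
#'
#' @param path Path to a `.wav` file.
#' @return A list with elements `samples` (numeric vector), `fs` (sampling
#'   rate, Hz) and `bit_depth` (16 or 32).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        fs       = readBin(body[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1L, size = 2L, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L) # skip unknown chunk (padded to even)
      next
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$channels != 1L) {
    stop("expected mono audio, got ", fmt$channels, " channels: ", path)
  }

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L,
                 size = 2L, endian = "little", signed = TRUE)
    samples <- x / 32767
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    samples <- readBin(data_raw, "double", length(data_raw) %/% 4L,
                       size = 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding (format=", fmt$format,
         ", bits=", fmt$bits, "): ", path)
  }
  list(samples = as.numeric(samples), fs = fmt$fs, bit_depth = fmt$bits)
}

#' Write a mono RIFF WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @param bit_depth 16 (integer PCM, the default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, bit_depth = 16) {
  stopifnot(bit_depth %in% c(16, 32), fs > 0)
  samples <- pmin(1, pmax(-1, as.numeric(samples)))
  n <- length(samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little") # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bit_depth == 16) {
    writeBin(as.integer(round(samples * 32767)), con, size = 2L, endian = "little")
  } else {
    writeBin(samples, con, size = 4L, endian = "little")
  }
  invisible(path)
}
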