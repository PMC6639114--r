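#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' @param wave a `phonocat_wave` (samples in \[-1, 1\]; values outside are
#'   clipped).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "phonocat_wave"))
  x <- pmax(-1, pmin(1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(wave$sample_rate)
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path file path.
#' @return a `phonocat_wave`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAV file", call. = FALSE)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only PCM mono WAV is supported", call. = FALSE)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", size - 8)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  structure(list(samples = pcm / 32767, sample_rate = fs),
            class = "phonocat_wave")
}
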