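## Minimal mono PCM16 WAV codec (RIFF/WAVE, little-endian).

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to [-1, 1] and quantized to 16-bit PCM.
#'
#' @param x numeric vector of samples in [-1, 1] (values outside are
#'   clipped with a warning).
#' @param sample_rate sampling rate, Hz.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeWhoopWav <- function(x, sample_rate, path) {
  if (max(abs(x)) > 1) {
    warning("writeWhoopWav: samples outside [-1, 1] clipped")
    x <- pmin(pmax(x, -1), 1)
  }
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path (mono PCM16 as written by
#'   \code{\link{writeWhoopWav}}; other chunk layouts are skipped over).
#' @param metadata optional metadata list attached to the record.
#' @return a \linkS4class{WhoopRecord} with samples scaled to [-1, 1].
#' @export
readWhoopWav <- function(path, metadata = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("readWhoopWav: not a RIFF/WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2L, size = 2, signed = TRUE,
                     endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(pcm) || is.null(rate))
    stop("readWhoopWav: missing fmt or data chunk: ", path)
  if (!identical(channels, 1L) || !identical(bits, 16L))
    stop("readWhoopWav: only mono 16-bit PCM supported (got ", channels,
         " channel(s), ", bits, " bits)")
  whoopRecord(pcm / 32767, rate, metadata)
}
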