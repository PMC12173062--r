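# Minimal RIFF/WAVE PCM-16 mono I/O. Only the dialect the pipeline uses
# (mono, 16-bit, arbitrary rate); samples are exchanged as doubles in [-1, 1].

#' Write a mono 16-bit PCM WAV file
#'
#' @param wave Numeric vector of samples in `[-1, 1]` (values are clipped).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(wave, sample_rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path File written by [write_wav()] (or any mono PCM-16 RIFF file).
#' @return List with `wave` (doubles in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little", signed = TRUE)
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
}
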