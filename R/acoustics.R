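# Long-term mean spectrogram of continuous hydrophone audio, plus a
# minimal PCM 16-bit RIFF/WAVE reader and writer (mono or first channel).

#' Read a PCM 16-bit WAV file
#'
#' Minimal RIFF/WAVE parser for uncompressed 16-bit PCM. Multi-channel
#' files return channel 1. Samples are scaled to `[-1, 1]`.
#'
#' @param path WAV file.
#' @return numeric waveform with attribute `fs` (sample rate, Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file", call. = FALSE)
  fs <- NULL; n_chan <- 1L; bits <- 16L; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz %/% 2, 2, endian = "little", signed = FALSE)
      n_chan <- fmt[2]; bits <- fmt[8]
      fs <- fmt[3] + 65536 * fmt[4]
    } else if (identical(id, "data")) {
      if (bits != 16L) stop("only 16-bit PCM is supported", call. = FALSE)
      data <- readBin(con, "integer", sz %/% 2, 2, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(fs) || is.null(data)) stop("malformed WAV file", call. = FALSE)
  if (n_chan > 1L) data <- data[seq(1, length(data), by = n_chan)]
  x <- data / 32768
  attr(x, "fs") <- fs
  x
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param x waveform in `[-1, 1]` (clipped).
#' @param path output file.
#' @param fs sample rate, Hz; defaults to the waveform's `fs` attribute.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = attr(x, "fs")) {
  if (is.null(fs)) stop("sample rate 'fs' required", call. = FALSE)
  pcm <- as.integer(round(pmin(pmax(x, -1), 32767 / 32768) * 32768))
  con <- file(path, "wb"); on.exit(close(con))
  data_sz <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")            # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")           # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Long-term mean spectrogram
#'
#' Welch-style average of magnitude-squared FFTs within coarse time bins:
#' Hann-windowed segments of `fft_size` samples with 50% overlap are
#' averaged (mean) inside each `time_resolution`-second bin, rows are
#' restricted to `band`, and power is reported in dB re digital full scale
#' (no hydrophone calibration). The deployment convention is a 10-s bin,
#' 1024-point FFT, 20 Hz to 43 kHz band at 96 kHz sampling.
#'
#' @param audio waveform in `[-1, 1]`.
#' @param fs sample rate, Hz; defaults to `attr(audio, "fs")`.
#' @param fft_size FFT length (default 1024; frequency bin width `fs/fft_size`).
#' @param time_resolution_s seconds per spectrogram column (default 10).
#' @param band `c(lo, hi)` Hz; an upper edge above Nyquist is clipped with a
#'   warning.
#' @return a `spectrogram_matrix`: list with `power_db` (freq x time),
#'   `frequency_hz`, `time_s` (bin centers), `fft_size`, `band`, `fs`.
#' @export
long_term_spectrogram <- function(audio, fs = attr(audio, "fs"), fft_size = 1024L,
                                  time_resolution_s = 10,
                                  band = c(20, 43000)) {
  if (is.null(fs)) stop("sample rate 'fs' required", call. = FALSE)
  if (length(audio) < time_resolution_s * fs)
    stop("audio shorter than one time bin", call. = FALSE)
  if (band[2] > fs / 2) {
    warning(sprintf("band upper edge %g Hz clipped to Nyquist %g Hz", band[2], fs / 2))
    band[2] <- fs / 2
  }
  win <- 0.5 * (1 - cos(2 * pi * seq_len(fft_size) / (fft_size + 1)))  # Hann
  wss <- sum(win^2)
  hop <- fft_size %/% 2L
  freqs <- (seq_len(fft_size %/% 2 + 1) - 1) * fs / fft_size
  rows <- which(freqs >= band[1] & freqs <= band[2])
  n_bins <- floor(length(audio) / (time_resolution_s * fs))
  bin_len <- as.integer(time_resolution_s * fs)
  pw <- matrix(NA_real_, length(rows), n_bins)
  for (b in seq_len(n_bins)) {
    seg <- audio[((b - 1L) * bin_len + 1L):(b * bin_len)]
    starts <- seq(1L, length(seg) - fft_size + 1L, by = hop)
    acc <- numeric(fft_size %/% 2 + 1)
    for (s in starts) {
      xf <- stats::fft(seg[s:(s + fft_size - 1L)] * win)
      p <- Mod(xf[seq_len(fft_size %/% 2 + 1)])^2
      acc <- acc + p
    }
    # one-sided mean power spectrum, window-power normalized
    spec <- acc / length(starts) / (wss * fs)
    spec[2:(length(spec) - 1)] <- 2 * spec[2:(length(spec) - 1)]
    pw[, b] <- spec[rows]
  }
  structure(list(power_db = 10 * log10(pmax(pw, 1e-300)),
                 frequency_hz = freqs[rows],
                 time_s = (seq_len(n_bins) - 0.5) * time_resolution_s,
                 fft_size = as.integer(fft_size), band = band, fs = fs),
            class = "spectrogram_matrix")
}

#' @export
print.spectrogram_matrix <- function(x, ...) {
  cat(sprintf("<spectrogram: %d freq bins (%g-%g Hz) x %d time bins, FFT %d>\n",
              length(x$frequency_hz), min(x$frequency_hz), max(x$frequency_hz),
              length(x$time_s), x$fft_size))
  invisible(x)
}
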