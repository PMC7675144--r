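#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16- or 24-bit mono PCM, the fixture format
#' used by the spectrogram frontend. Samples are returned normalized to
#' \[-1, 1\].
#'
#' @param path path to a WAV file.
#' @return list with `samples` (numeric vector in \[-1, 1\]) and
#'   `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_audenc("not a RIFF/WAVE file", "audenc_format_error")
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      n_channels <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      if (audio_format != 1) {
        stop_audenc("only uncompressed PCM WAV is supported", "audenc_format_error")
      }
      if (n_channels != 1) {
        stop_audenc("only mono WAV is supported", "audenc_format_error")
      }
      fmt <- list(sample_rate = sample_rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_audenc("WAV data chunk before fmt chunk", "audenc_format_error")
      if (fmt$bits == 16) {
        n <- size %/% 2
        samples <- readBin(con, "integer", n, 2, endian = "little") / 32768
      } else if (fmt$bits == 24) {
        raw <- readBin(con, "raw", size)
        n <- length(raw) %/% 3
        b <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else {
        stop_audenc("only 16- or 24-bit PCM WAV is supported", "audenc_format_error")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + (size %% 2)))
    }
  }
  if (is.null(samples)) stop_audenc("no data chunk found in WAV file", "audenc_format_error")
  list(samples = samples, sample_rate_hz = fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in \[-1, 1\] (values outside are clipped).
#' @param sample_rate_hz sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path) {
  pcm <- as.integer(round(pmin(1, pmax(-1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# Equivalent rectangular bandwidth of the auditory filter at center
# frequency f (Glasberg & Moore parameterization).
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# Truncated FIR impulse response of an order-n gammatone filter, scaled to
# unit magnitude response at its center frequency.
gammatone_kernel <- function(fc, fs, order = 2) {
  b <- 1.019 * erb_hz(fc)
  decay <- 2 * pi * b
  t_max <- min(0.06, 12 / decay)
  t <- seq(0, t_max, by = 1 / fs)
  g <- t^(order - 1) * exp(-decay * t) * cos(2 * pi * fc * t)
  resp <- sum(g * exp(-2i * pi * fc * t))
  g / Mod(resp)
}

#' Gammatone log-spectrogram of a waveform
#'
#' Converts a sound waveform into the channels x time log-level matrix used
#' as input by all encoding models: an order-2 gammatone filterbank with
#' log-spaced center frequencies, half-wave rectified envelopes smoothed by a
#' 4th-order 30-Hz low-pass, down-sampled to the PSTH bin rate (100 Hz), and
#' log-compressed with a fixed floor.
#'
#' @param waveform numeric vector of PCM samples in \[-1, 1\], or the list
#'   returned by [read_wav()].
#' @param sample_rate_hz sampling rate of `waveform` in Hz (ignored when
#'   `waveform` comes from [read_wav()]). Must be at least `2 * f_high`.
#' @param n_channels number of filterbank channels (default 18).
#' @param f_low,f_high lowest and highest center frequency in Hz.
#' @param bin_s output bin width in seconds (default 0.01, i.e. 100 Hz).
#' @return a [spectrogram()] with `n_channels` rows and
#'   `ceiling(duration / bin_s)` columns. Digital silence maps to the
#'   compression floor (level 0).
#' @examples
#' fs <- 44100
#' tone <- sin(2 * pi * 1000 * seq(0, 0.2, by = 1 / fs))
#' sp <- gammatone_spectrogram(tone, fs)
#' dim(sp$levels)
#' @export
gammatone_spectrogram <- function(waveform, sample_rate_hz = NULL,
                                  n_channels = 18, f_low = 200, f_high = 20000,
                                  bin_s = 0.01) {
  if (is.list(waveform)) {
    sample_rate_hz <- waveform$sample_rate_hz
    waveform <- waveform$samples
  }
  if (is.null(sample_rate_hz)) {
    stop_audenc("`sample_rate_hz` is required", "audenc_config_error")
  }
  if (sample_rate_hz < 2 * f_high) {
    stop_audenc(sprintf(
      "sample rate %g Hz violates the Nyquist requirement of at least %g Hz for f_high = %g Hz",
      sample_rate_hz, 2 * f_high, f_high
    ), "audenc_nyquist_error")
  }
  fs <- sample_rate_hz
  n <- length(waveform)
  duration <- n / fs
  n_bins <- ceiling(duration / bin_s)
  centers <- log_spaced_centers(n_channels, f_low, f_high)

  # envelope smoothing filter: 4th-order Butterworth low-pass at 30 Hz
  bt <- signal::butter(4, 30 / (fs / 2), type = "low")
  # sample each 10-ms bin at its center
  idx <- pmin(n, pmax(1, round(((seq_len(n_bins) - 0.5) * bin_s) * fs)))

  env <- matrix(0, n_channels, n_bins)
  for (ch in seq_len(n_channels)) {
    kern <- gammatone_kernel(centers[ch], fs)
    y <- signal::fftfilt(kern, waveform)
    y <- pmax(y, 0)                       # half-wave rectification
    y <- signal::filter(bt, y)
    env[ch, ] <- pmax(as.numeric(y)[idx], 0)
  }

  # log compression with floor at a fixed fraction of full-scale RMS
  x0 <- 1e-3 * (1 / sqrt(2))
  levels <- log10(env + x0) - log10(x0)
  spectrogram(levels, centers, bin_s)
}
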