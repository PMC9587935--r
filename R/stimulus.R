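#' Amplitude-modulated broadband target stimulus
#'
#' Synthesizes the target sound: a broadband (white Gaussian) noise burst
#' with a sinusoidal amplitude envelope. At modulation depth `m` the
#' envelope oscillates between `1 - m` and `1` (80% depth: between 0.2 and
#' 1); the waveform is peak-normalized to unit amplitude. The modulation
#' rate is a free parameter of the synthesis (default 2 Hz) - the original
#' burst's AM rate and carrier spectrum are not constrained here.
#'
#' @param duration_s Burst duration, seconds (default 3).
#' @param mod_depth Modulation depth in \[0, 1\] (default 0.8).
#' @param sample_rate Audio sampling rate, Hz.
#' @param mod_rate_hz Envelope frequency, Hz.
#' @return Numeric waveform of `round(duration_s * sample_rate)` samples in
#'   \[-1, 1\], with attributes `sample_rate` and `envelope`.
#' @export
generate_stimulus <- function(duration_s = 3.0, mod_depth = 0.8,
                              sample_rate = 44100, mod_rate_hz = 2) {
  if (mod_depth < 0 || mod_depth > 1)
    stop("mod_depth must lie in [0, 1]", call. = FALSE)
  if (duration_s <= 0 || sample_rate <= 0)
    stop("duration and sample rate must be positive", call. = FALSE)
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  env <- (1 - mod_depth) + mod_depth * (1 + sin(2 * pi * mod_rate_hz * t - pi / 2)) / 2
  x <- stats::rnorm(n) * env
  x <- x / max(abs(x))
  attr(x, "sample_rate") <- sample_rate
  attr(x, "envelope") <- env
  x
}

#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (no audio package dependency): one channel,
#' 16-bit little-endian PCM.
#'
#' @param x Numeric waveform in \[-1, 1\].
#' @param path Output file path.
#' @param sample_rate Sampling rate, Hz (default: the waveform's
#'   `sample_rate` attribute).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = attr(x, "sample_rate")) {
  if (is.null(sample_rate)) stop("sample_rate is required", call. = FALSE)
  pcm <- as.integer(round(pmax(-1, pmin(1, as.numeric(x))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
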