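#' Specification of a 40 Hz amplitude-modulated tone
#'
#' Parameter container for the auditory steady-state stimulus: a sinusoidal
#' carrier multiplied by a raised cosine envelope,
#' \deqn{A(t) = \sin(2\pi f_c t)\,(1 + m \cos(2\pi f_m t)),}
#' with carrier frequency `f_c` (default 1000 Hz), modulation depth `m`
#' (default 1), modulation frequency `f_m` (default 40 Hz), 1 s duration and
#' a 44.1 kHz audio sampling rate.
#'
#' @param carrier_freq_hz carrier frequency in Hz, positive.
#' @param mod_freq_hz modulation frequency in Hz, positive.
#' @param mod_depth modulation depth in `[0, 1]`.
#' @param duration_s stimulus duration in seconds, positive.
#' @param sample_rate_hz audio sampling rate in Hz, positive.
#' @return object of class `am_tone_spec`.
#' @seealso [generate_am_tone()]
#' @export
am_tone_spec <- function(carrier_freq_hz = 1000, mod_freq_hz = 40, mod_depth = 1,
                         duration_s = 1, sample_rate_hz = 44100) {
  if (!is.numeric(carrier_freq_hz) || carrier_freq_hz <= 0)
    stop_assr("carrier_freq_hz must be positive (got %s)", carrier_freq_hz)
  if (!is.numeric(mod_freq_hz) || mod_freq_hz <= 0)
    stop_assr("mod_freq_hz must be positive (got %s)", mod_freq_hz)
  if (!is.numeric(mod_depth) || mod_depth < 0 || mod_depth > 1)
    stop_assr("mod_depth must lie in [0, 1] (got %s)", mod_depth)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_assr("duration_s must be positive (got %s)", duration_s)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop_assr("sample_rate_hz must be positive (got %s)", sample_rate_hz)
  structure(list(carrier_freq_hz = carrier_freq_hz, mod_freq_hz = mod_freq_hz,
                 mod_depth = mod_depth, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz),
            class = "am_tone_spec")
}

#' Synthesize an amplitude-modulated tone
#'
#' Evaluates the stimulus waveform on the sample grid `t_i = i / rate`,
#' `i = 0, 1, ...`, with `round(duration * rate)` samples. Raw amplitudes are
#' kept (peak can reach `1 + mod_depth`); scaling happens only at audio
#' export. An optional raised-cosine onset/offset ramp is available but off
#' by default.
#'
#' @param spec an [am_tone_spec()].
#' @param ramp_s duration in seconds of a cosine onset/offset ramp; `0`
#'   (default) applies no ramp.
#' @return object of class `waveform`: list with `samples` and
#'   `sample_rate_hz`.
#' @examples
#' w <- generate_am_tone(am_tone_spec())
#' sqrt(mean(w$samples^2))  # ~ sqrt(0.75)
#' @export
generate_am_tone <- function(spec, ramp_s = 0) {
  stopifnot(inherits(spec, "am_tone_spec"))
  n <- round(spec$duration_s * spec$sample_rate_hz)
  t <- (seq_len(n) - 1) / spec$sample_rate_hz
  s <- sin(2 * pi * spec$carrier_freq_hz * t) *
    (1 + spec$mod_depth * cos(2 * pi * spec$mod_freq_hz * t))
  if (ramp_s > 0) {
    nr <- min(n %/% 2, round(ramp_s * spec$sample_rate_hz))
    if (nr > 0) {
      ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr))
      s[seq_len(nr)] <- s[seq_len(nr)] * ramp
      s[n - seq_len(nr) + 1] <- s[n - seq_len(nr) + 1] * ramp
    }
  }
  structure(list(samples = s, sample_rate_hz = spec$sample_rate_hz),
            class = "waveform")
}

#' Spectral quality control of an AM tone
#'
#' Locates the dominant spectral peaks of the waveform by discrete Fourier
#' transform. For an amplitude-modulated tone the spectrum concentrates at
#' the carrier `f_c` and the two modulation sidebands `f_c - f_m` and
#' `f_c + f_m`, each sideband carrying `m/2` of the carrier magnitude; for
#' `m = 0` only the carrier remains.
#'
#' @param wave a `waveform`.
#' @param spec the [am_tone_spec()] the waveform was generated from (used to
#'   check that at least one modulation period is available).
#' @param n_peaks number of dominant peaks to report (local maxima of the
#'   magnitude spectrum, largest first).
#' @return data.frame with columns `freq_hz`, `magnitude` and
#'   `rel_magnitude` (relative to the strongest peak), ordered by decreasing
#'   magnitude.
#' @export
validate_spectrum <- function(wave, spec, n_peaks = 3L) {
  stopifnot(inherits(wave, "waveform"), inherits(spec, "am_tone_spec"))
  n <- length(wave$samples)
  if (n < wave$sample_rate_hz / spec$mod_freq_hz)
    stop_assr("waveform shorter than one modulation period (%d samples < %.1f)",
              n, wave$sample_rate_hz / spec$mod_freq_hz)
  mag <- Mod(stats::fft(wave$samples))[seq_len(n %/% 2 + 1L)]
  freqs <- (seq_along(mag) - 1) * wave$sample_rate_hz / n
  # local maxima of the one-sided magnitude spectrum
  is_peak <- c(FALSE, mag[2:(length(mag) - 1)] > mag[1:(length(mag) - 2)] &
                 mag[2:(length(mag) - 1)] >= mag[3:length(mag)], FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0L) cand <- which.max(mag)
  ord <- cand[order(mag[cand], decreasing = TRUE)]
  top <- ord[seq_len(min(n_peaks, length(ord)))]
  # discard peaks that are numerical dust relative to the strongest one
  top <- top[mag[top] > 1e-6 * mag[top[1]]]
  data.frame(freq_hz = freqs[top], magnitude = mag[top],
             rel_magnitude = mag[top] / mag[top[1]])
}

#' Write a waveform to a WAV file
#'
#' Minimal mono RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE
#' float. By default the waveform is peak-normalized to 0.95 full scale for
#' export (presentation level is a hardware calibration matter); the
#' in-memory amplitudes are untouched.
#'
#' @param wave a `waveform` with finite samples.
#' @param path output file path.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @param normalize peak-normalize before writing (default `TRUE`).
#' @param peak_level target peak amplitude when normalizing (default 0.95).
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(wave, path, format = c("pcm16", "float32"),
                      normalize = TRUE, peak_level = 0.95) {
  stopifnot(inherits(wave, "waveform"))
  format <- match.arg(format)
  s <- wave$samples
  if (length(s) == 0L) stop_assr("cannot write an empty waveform")
  if (!all(is.finite(s))) stop_assr("waveform contains non-finite samples")
  if (normalize) {
    pk <- max(abs(s))
    if (pk > 0) s <- s * (peak_level / pk)
  }
  rate <- as.integer(round(wave$sample_rate_hz))
  bits <- if (format == "pcm16") 16L else 32L
  fmt_code <- if (format == "pcm16") 1L else 3L
  block <- bits %/% 8L
  data_bytes <- length(s) * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * block), con, size = 4, endian = "little") # byte rate
  writeBin(block, con, size = 2, endian = "little")        # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(-1, pmin(1, s)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(s), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return a `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop_assr("not a RIFF/WAVE file: %s", path)
  fmt_code <- NULL; rate <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop_assr("no data chunk found in %s", path)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      n_chan <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (n_chan != 1L) stop_assr("only mono WAV supported (got %d channels)", n_chan)
      if (sz > 16L) readBin(con, "raw", n = sz - 16L)
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) stop_assr("data chunk before fmt chunk in %s", path)
      n <- sz %/% (bits %/% 8L)
      s <- if (fmt_code == 1L && bits == 16L) {
        readBin(con, "integer", n = n, size = 2, endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else stop_assr("unsupported WAV format code %d / %d bits", fmt_code, bits)
      return(structure(list(samples = s, sample_rate_hz = rate), class = "waveform"))
    } else {
      readBin(con, "raw", n = sz)
    }
  }
}
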