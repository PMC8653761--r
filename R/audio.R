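#' Spectrogram measurement settings
#'
#' The spectrographic convention used for syllable measurement: a Hann
#' analysis window of 512 samples with 95% overlap, and a detection
#' threshold 20 dB above the background noise level.
#'
#' @param window_length FFT window length in samples (power of two).
#' @param overlap_pct window overlap in percent, in `[0, 100)`.
#' @param threshold_db detection threshold in dB above background.
#' @return a list of class `"spectrogram_params"`.
#' @export
spectrogram_params <- function(window_length = 512L, overlap_pct = 95,
                               threshold_db = 20) {
  stopifnot(overlap_pct >= 0, overlap_pct < 100)
  if (bitwAnd(window_length, window_length - 1L) != 0L)
    stop("window length must be a power of two")
  structure(list(window_length = as.integer(window_length),
                 overlap_pct = overlap_pct, threshold_db = threshold_db),
            class = "spectrogram_params")
}

#' Render a synthetic syllable as audio
#'
#' Produces a linear frequency sweep (or pure tone when the frequency bounds
#' coincide) spanning the segment's time and frequency extent, embedded in
#' low-level white noise — a controllable fixture for spectrogram-based
#' measurement.
#'
#' @param segment a list or one-row data frame with `onset_s`, `offset_s`,
#'   `f_min_kHz`, `f_max_kHz`.
#' @param sample_rate sampling rate in Hz (recording standard: 48 kHz).
#' @param amplitude peak amplitude of the sweep in `(0, 1]`.
#' @param noise_db noise floor relative to the signal peak, in dB (negative).
#' @param pad_s silent (noise-only) padding before the onset and after the
#'   offset.
#' @param seed seed for the noise floor.
#' @return a list of class `"sv_wave"`: `samples` in `[-1, 1]` and
#'   `sample_rate`.
#' @export
render_syllable_audio <- function(segment, sample_rate = 48000,
                                  amplitude = 0.8, noise_db = -40,
                                  pad_s = 0.15, seed = 1L) {
  if (amplitude <= 0) stop("zero or negative amplitude requested")
  f0 <- segment$f_min_kHz * 1000
  f1 <- segment$f_max_kHz * 1000
  if (max(f0, f1) >= sample_rate / 2)
    stop("frequency above the Nyquist limit")
  if (segment$offset_s <= segment$onset_s)
    stop("invalid segment: offset must exceed onset")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  total <- segment$offset_s + pad_s
  t <- seq(0, total, by = 1 / sample_rate)
  x <- stats::rnorm(length(t), 0, amplitude * 10^(noise_db / 20))
  inside <- t >= segment$onset_s & t < segment$offset_s
  ts <- t[inside] - segment$onset_s
  dur <- segment$offset_s - segment$onset_s
  # linear chirp: instantaneous frequency f0 -> f1 over the segment;
  # a 5 ms raised-cosine ramp at each edge avoids broadband onset clicks
  phase <- 2 * pi * (f0 * ts + (f1 - f0) / (2 * dur) * ts^2)
  ramp <- min(0.005, dur / 4)
  env <- pmin(1, ts / ramp, (dur - ts) / ramp)
  env <- (1 - cos(pi * pmax(0, pmin(1, env)))) / 2
  x[inside] <- x[inside] + amplitude * env * sin(phase)
  structure(list(samples = x / max(1, max(abs(x))),
                 sample_rate = sample_rate), class = "sv_wave")
}

#' Write / read 16-bit PCM mono WAV
#'
#' Minimal single-channel PCM I/O for the audio fixtures (no audio package
#' is required at run time).
#'
#' @param wave an `"sv_wave"` (list with `samples`, `sample_rate`).
#' @param path file path.
#' @return `write_wav` returns `path` invisibly; `read_wav` an `"sv_wave"`.
#' @export
write_wav <- function(wave, path) {
  s <- pmax(-1, pmin(1, wave$samples))
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM format
  writeBin(1L, con, size = 2, endian = "little")            # channels
  writeBin(as.integer(wave$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * 2L), con, size = 4,
           endian = "little")                               # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file")
  sr <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono 16-bit PCM is supported")
      sr <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      samples <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                         endian = "little") / 32767
      break
    } else invisible(readBin(con, "raw", sz))
  }
  if (is.null(sr) || is.null(samples)) stop("malformed WAV file")
  structure(list(samples = samples, sample_rate = sr), class = "sv_wave")
}

#' Measure a syllable from audio by thresholded spectrogram
#'
#' Computes a Hann-window short-time Fourier spectrogram of the waveform and
#' measures the annotated region the way syllables are measured on
#' spectrograms: the background level is the median spectral power outside
#' the region; time and frequency boundaries are taken where power exceeds
#' background by `threshold_db`; the mean frequency is the average of the
#' per-window peak frequencies between onset and offset (dominant frequency
#' only, no harmonic tracking).
#'
#' @param wave an `"sv_wave"`.
#' @param region numeric `c(start_s, end_s)` containing the syllable; must
#'   lie within the waveform and leave audio outside for the background
#'   estimate.
#' @param params a [spectrogram_params()].
#' @return one-row data frame: `onset_s`, `offset_s`, `f_min_kHz`,
#'   `f_max_kHz`, `f_mean_kHz`.
#' @export
measure_syllable <- function(wave, region, params = spectrogram_params()) {
  sr <- wave$sample_rate
  nwin <- params$window_length
  if (diff(region) * sr < nwin)
    stop("annotated region is shorter than one analysis window")
  if (region[1] < 0 || region[2] > length(wave$samples) / sr)
    stop("region lies outside the waveform")
  hop <- max(1L, round(nwin * (1 - params$overlap_pct / 100)))
  sp <- signal::specgram(wave$samples, n = nwin, Fs = sr,
                         window = signal::hanning(nwin),
                         overlap = nwin - hop)
  pw <- 20 * log10(Mod(sp$S) + 1e-300)
  tt <- sp$t            # window start times, s
  ff <- sp$f            # Hz
  t_mid <- tt + nwin / (2 * sr)

  out_cols <- t_mid < region[1] | t_mid > region[2]
  if (!any(out_cols))
    stop("no audio outside the annotated region to estimate background")
  bg <- stats::median(pw[, out_cols])
  thr <- bg + params$threshold_db

  in_cols <- which(t_mid >= region[1] & t_mid <= region[2])
  active <- in_cols[apply(pw[, in_cols, drop = FALSE], 2, max) > thr]
  if (length(active) == 0L)
    stop("no signal detected above threshold in the annotated region")

  onset <- tt[active[1]]
  offset <- tt[active[length(active)]] + nwin / sr
  sub <- pw[, active, drop = FALSE]
  hot <- which(sub > thr, arr.ind = TRUE)
  f_min <- min(ff[hot[, 1]]); f_max <- max(ff[hot[, 1]])
  peak_f <- ff[apply(sub, 2, which.max)]
  data.frame(onset_s = onset, offset_s = offset,
             f_min_kHz = f_min / 1000, f_max_kHz = f_max / 1000,
             f_mean_kHz = mean(peak_f) / 1000)
}
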