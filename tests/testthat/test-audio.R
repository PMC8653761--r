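test_that("spectrogram parameters are validated", {
  p <- spectrogram_params()
  expect_equal(p$window_length, 512L)
  expect_equal(p$overlap_pct, 95)
  expect_error(spectrogram_params(window_length = 500), "power of two")
  expect_error(spectrogram_params(overlap_pct = 100), "overlap")
})

test_that("rendering validates frequency and amplitude", {
  seg <- data.frame(onset_s = 0.1, offset_s = 0.3,
                    f_min_kHz = 30, f_max_kHz = 30)
  expect_error(render_syllable_audio(seg), "Nyquist")
  seg$f_min_kHz <- seg$f_max_kHz <- 4
  expect_error(render_syllable_audio(seg, amplitude = 0), "amplitude")
  bad <- transform(seg, offset_s = 0.1)
  expect_error(render_syllable_audio(bad), "offset")
})

test_that("WAV files round-trip losslessly at 16-bit precision", {
  seg <- data.frame(onset_s = 0.2, offset_s = 0.45,
                    f_min_kHz = 4, f_max_kHz = 4)
  w <- render_syllable_audio(seg)
  path <- file.path(tempdir(), "syll.wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 48000)
  expect_equal(length(back$samples), length(w$samples))
  expect_lt(max(abs(back$samples - w$samples)), 1 / 32000)
  unlink(path)
})

test_that("a pure tone is measured at its time and frequency bounds", {
  seg <- data.frame(onset_s = 0.2, offset_s = 0.45,
                    f_min_kHz = 4, f_max_kHz = 4)
  m <- measure_syllable(render_syllable_audio(seg), region = c(0.1, 0.55))
  expect_lt(abs(m$onset_s - 0.2), 0.025)
  expect_lt(abs(m$offset_s - 0.45), 0.025)
  expect_lt(abs(m$f_mean_kHz - 4), 0.15)
  # bounds within the Hann main-lobe smear of the analysis window
  expect_lt(abs(m$f_min_kHz - 4), 0.45)
  expect_lt(abs(m$f_max_kHz - 4), 0.45)
})

test_that("a linear sweep is measured across its frequency extent", {
  seg <- data.frame(onset_s = 0.2, offset_s = 0.5,
                    f_min_kHz = 3, f_max_kHz = 5)
  m <- measure_syllable(render_syllable_audio(seg), region = c(0.1, 0.6))
  expect_lt(abs(m$onset_s - 0.2), 0.025)
  expect_lt(abs(m$offset_s - 0.5), 0.025)
  expect_lt(abs(m$f_min_kHz - 3), 0.45)
  expect_lt(abs(m$f_max_kHz - 5), 0.45)
  expect_lt(abs(m$f_mean_kHz - 4), 0.2)
})

test_that("measurement fails cleanly on silence and bad regions", {
  set.seed(30)
  noise <- structure(list(samples = rnorm(48000, 0, 1e-4),
                          sample_rate = 48000), class = "sv_wave")
  expect_error(measure_syllable(noise, c(0.3, 0.6)), "no signal")
  seg <- data.frame(onset_s = 0.2, offset_s = 0.45,
                    f_min_kHz = 4, f_max_kHz = 4)
  w <- render_syllable_audio(seg)
  expect_error(measure_syllable(w, c(0.3, 0.305)), "window")
  expect_error(measure_syllable(w, c(0.1, 99)), "outside the waveform")
  expect_error(measure_syllable(w, c(0, length(w$samples) / 48000)),
               "background")
})

test_that("measured syllables feed the trait pipeline consistently", {
  segs <- data.frame(onset_s = c(0.2, 0.6), offset_s = c(0.35, 0.78),
                     f_min_kHz = c(3, 5), f_max_kHz = c(4, 6))
  measured <- do.call(rbind, lapply(1:2, function(i) {
    w <- render_syllable_audio(segs[i, ], seed = i)
    measure_syllable(w, c(segs$onset_s[i] - 0.1, segs$offset_s[i] + 0.1))
  }))
  measured$recording_id <- "r1"
  measured$song_index <- 1
  tr <- song_traits(measured, complexity = FALSE)
  expect_lt(abs(tr$song_length_s - (0.78 - 0.2)), 0.05)
  expect_lt(abs(tr$f_min_kHz - 3.5), 0.2)   # mean frequencies
  expect_lt(abs(tr$f_max_kHz - 5.5), 0.2)
})
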