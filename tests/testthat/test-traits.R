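make_song <- function(onsets, durations, f_mean, labels = NULL) {
  d <- data.frame(onset_s = onsets, offset_s = onsets + durations,
                  f_min_kHz = f_mean - 0.2, f_max_kHz = f_mean + 0.2,
                  f_mean_kHz = f_mean)
  if (!is.null(labels)) d$type_label <- labels
  d
}

test_that("song traits match hand-computed values", {
  # 5 syllables, 3 distinct types, spanning exactly 4 s, 10 syllables/4 s
  s <- make_song(onsets = seq(0, 3.9, length.out = 10),
                 durations = 0.1, f_mean = rep(c(3, 4, 5), length.out = 10),
                 labels = rep(c("a", "b", "c"), length.out = 10))
  tr <- song_traits(s)
  expect_equal(tr$song_length_s, 4)
  expect_equal(tr$tempo_per_s, 2.5)
  expect_equal(tr$f_min_kHz, 3)
  expect_equal(tr$f_max_kHz, 5)
  expect_equal(tr$f_mean_kHz, mean(rep(c(3, 4, 5), length.out = 10)))
  expect_equal(tr$bandwidth_kHz, 2)

  s5 <- make_song(0:4, 0.1, rep(4, 5), labels = c("a", "b", "c", "a", "b"))
  expect_equal(song_traits(s5)$complexity, 3 / 5)
  # all distinct -> complexity exactly 1
  s_all <- make_song(0:4, 0.1, rep(4, 5), labels = letters[1:5])
  expect_equal(song_traits(s_all)$complexity, 1)
})

test_that("song traits validate their input", {
  expect_error(song_traits(make_song(numeric(0), numeric(0), numeric(0))),
               "no syllables")
  bad <- make_song(0:2, 0.1, rep(4, 3))
  bad$offset_s[2] <- bad$onset_s[2]
  expect_error(song_traits(bad, complexity = FALSE), "offset")
  expect_error(song_traits(make_song(0:2, 0.1, rep(4, 3))), "labels")
})

test_that("recording traits average songs and compute song rate", {
  songs <- do.call(rbind, lapply(0:19, function(i) {
    s <- make_song(i * 20 + seq(0, 3.9, length.out = 12), 0.1, rep(4, 12),
                   labels = rep(c("a", "b"), 6))
    s$song_index <- i + 1
    s
  }))
  rt <- recording_traits(songs)
  # start-to-start spacing 20 s -> 3 songs per minute
  expect_equal(rt$song_rate_per_min, 3)
  expect_equal(rt$song_length_s, 4)
  expect_equal(rt$repertoire_size, 2)
  # gap mode: silent gap 20 - 4 = 16 s -> 60/16
  rt_gap <- recording_traits(songs, interval = "gap")
  expect_equal(rt_gap$song_rate_per_min, 60 / 16)
  expect_warning(recording_traits(songs[songs$song_index <= 5, ]),
                 "5 songs")
})

test_that("recording means are invariant to song order, song rate is not", {
  set.seed(20)
  songs <- do.call(rbind, lapply(1:20, function(i) {
    s <- make_song(cumsum(runif(8, 0.3, 0.6)) + i^1.3 * 8, 0.1,
                   runif(8, 3, 6), labels = sample(letters[1:6], 8, TRUE))
    s$song_index <- i
    s
  }))
  shuffled <- songs
  perm <- sample(1:20)
  shuffled$song_index <- perm[shuffled$song_index]
  a <- recording_traits(songs)
  b <- recording_traits(shuffled)
  for (v in c("song_length_s", "tempo_per_s", "complexity", "f_mean_kHz",
              "bandwidth_kHz", "repertoire_size"))
    expect_equal(a[[v]], b[[v]])
})

test_that("k-means recovers well-separated repertoires exactly", {
  cfg <- sim_config(n_stimuli = 5, recordings_per_stimulus = 2, n_years = 2,
                    songs_per_recording = 5, repertoire_range = c(5, 12),
                    n_global_types = 60, proto_noise = 0,
                    freq_shift_sd = c(stimulus = 0, focal = 0, year = 0),
                    seed = 11)
  d <- simulate_design(cfg)
  cc <- simulate_corpus(d, cfg)
  est <- suppressMessages(estimate_repertoire(cc, k = 200))
  truth <- tapply(cc$type_true, cc$recording_id,
                  function(x) length(unique(x)))
  expect_equal(est$repertoire,
               unname(as.integer(truth[est$recording_id])))
})

test_that("repertoire estimate grows as distinct prototypes are added", {
  # one recording using 2, then 4, then 6 well-separated types
  proto <- data.frame(f = c(2, 3, 4, 5, 6, 7))
  build <- function(ntypes) {
    f <- rep(proto$f[1:ntypes], each = 4)
    s <- make_song(seq_along(f), 0.1, f)
    s$recording_id <- "r1"
    s$song_index <- 1
    s
  }
  sizes <- vapply(c(2, 4, 6), function(k)
    suppressMessages(estimate_repertoire(build(k)))$repertoire, integer(1))
  expect_true(all(diff(sizes) > 0))
  expect_equal(sizes, c(2L, 4L, 6L))
})

test_that("identical syllables collapse to a single type", {
  s <- make_song(1:30, 0.1, rep(4, 30))
  s$recording_id <- rep(c("a", "b"), 15)
  s$song_index <- 1
  est <- suppressMessages(estimate_repertoire(s))
  expect_equal(est$repertoire, c(1L, 1L))
})

test_that("clustering validates input and protects the caller's RNG", {
  expect_error(syllable_types(make_song(numeric(0), numeric(0),
                                        numeric(0))), "empty")
  bad <- make_song(0:3, 0.1, c(3, 4, NaN, 5))
  expect_error(syllable_types(bad), "non-finite")
  set.seed(77); before <- runif(1); set.seed(77)
  invisible(suppressMessages(syllable_types(make_song(0:9, 0.1,
                                                      rep(3:4, 5)))))
  expect_equal(runif(1), before)
})
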