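test_that("design generation is deterministic and correctly shaped", {
  cfg <- sim_config(seed = 1)
  d1 <- simulate_design(cfg)
  d2 <- simulate_design(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_design(cfg, seed = 2)
  expect_false(identical(d1, d3))

  expect_setequal(names(d1), c("recording_id", "focal_male_id",
                               "stimulus_id", "stimulus_sex", "year",
                               "date", "focal_age", "elapsed_min"))
  expect_equal(length(unique(d1$stimulus_id)), 20)
  expect_equal(nlevels(d1$year), 6)
  # each stimulus is used within a single year
  expect_true(all(tapply(d1$year, d1$stimulus_id,
                         function(x) length(unique(x))) == 1))
  expect_true(all(table(d1$stimulus_id) >= 1 & table(d1$stimulus_id) <= 15))
})

test_that("explicit per-stimulus recording counts are honored", {
  cfg <- sim_config(n_stimuli = 20,
                    recordings_per_stimulus = c(rep(5, 19), 6),
                    seed = 2)
  d <- simulate_design(cfg)
  expect_equal(nrow(d), 101)
  expect_equal(sort(as.integer(table(d$stimulus_id))),
               sort(c(rep(5L, 19), 6L)))
})

test_that("stimulus reuse follows the truncated geometric target", {
  cfg <- sim_config(n_stimuli = 3000, n_years = 6, seed = 3)
  d <- simulate_design(cfg)
  counts <- as.integer(table(d$stimulus_id))
  expect_true(all(counts >= 1 & counts <= 15))
  expect_equal(mean(counts), 3.33, tolerance = 0.1)
})

test_that("trait simulation carries its ground truth and hits the variances", {
  cfg <- sim_config(n_stimuli = 2000, seed = 4)
  d <- simulate_design(cfg)
  tr <- simulate_traits(d, cfg)
  expect_identical(tr, simulate_traits(d, cfg))
  gt <- attr(tr, "ground_truth")
  expect_named(gt$variances, c("focal", "stimulus", "year"))
  expect_equal(sum(unlist(gt$variances)) + gt$residual_variance, 3.581,
               tolerance = 1e-9)
  # law of large numbers on the drawn stimulus intercepts
  expect_equal(var(gt$intercepts$stimulus), 0.286, tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(variance_components = c(bogus = 1)), "grouping")
  expect_error(sim_config(repertoire_range = c(50, 300),
                          n_global_types = 240), "library")
  expect_error(simulate_design(sim_config(recordings_per_stimulus = 0)),
               "zero recordings")
  expect_error(sim_config(variance_components =
                            c(focal = -1, stimulus = 0, year = 0)),
               "non-negative")
})

test_that("corpus songs have the configured structure", {
  cfg <- sim_config(n_stimuli = 4, recordings_per_stimulus = 2, n_years = 2,
                    songs_per_recording = 6, repertoire_range = c(8, 12),
                    n_global_types = 60, seed = 5)
  d <- simulate_design(cfg)
  cc <- simulate_corpus(d, cfg)
  expect_identical(cc, simulate_corpus(d, cfg))
  expect_true(all(cc$offset_s > cc$onset_s))
  expect_true(all(cc$f_max_kHz >= cc$f_mean_kHz &
                  cc$f_mean_kHz >= cc$f_min_kHz & cc$f_min_kHz > 0))
  expect_equal(sort(unique(cc$song_index)), 1:6)
  per_rec <- tapply(cc$song_index, cc$recording_id,
                    function(x) length(unique(x)))
  expect_true(all(per_rec == 6))
  gt <- attr(cc, "ground_truth")
  expect_true(all(gt$repertoire_size >= 8 & gt$repertoire_size <= 12))
  # syllable durations near the 0.1 s standard
  expect_lt(abs(median(cc$offset_s - cc$onset_s) - 0.1), 0.02)
})

test_that("stimulus shift enters only the configured songs", {
  base <- list(n_stimuli = 10, recordings_per_stimulus = 3, n_years = 2,
               songs_per_recording = 10,
               length_shift_sd = c(stimulus = 1.5, focal = 0, year = 0),
               freq_shift_sd = c(stimulus = 0, focal = 0, year = 0),
               seed = 6)
  cfg <- do.call(sim_config, c(base, list(stimulus_effect_songs = 1:5)))
  d <- simulate_design(cfg)
  cc <- simulate_corpus(d, cfg)
  len <- tapply(cc$offset_s, list(cc$recording_id, cc$song_index), max) -
    tapply(cc$onset_s, list(cc$recording_id, cc$song_index), min)
  sd_early <- sd(rowMeans(len[, 1:5]))
  sd_late <- sd(rowMeans(len[, 6:10]))
  expect_gt(sd_early, 3 * sd_late)
})

test_that("segment tables round-trip through disk", {
  cfg <- sim_config(n_stimuli = 2, recordings_per_stimulus = 1, n_years = 1,
                    songs_per_recording = 3, repertoire_range = c(5, 8),
                    n_global_types = 40, seed = 7)
  d <- simulate_design(cfg)
  cc <- simulate_corpus(d, cfg)
  path <- file.path(tempdir(), "segments.tsv")
  write_segments(cc, path)
  back <- read_segments(path)
  expect_equal(back$onset_s, cc$onset_s, tolerance = 1e-9)
  expect_equal(back$recording_id, cc$recording_id)
  unlink(c(path, paste0(path, ".ground_truth.json")))
})
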