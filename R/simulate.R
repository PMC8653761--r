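#' Configuration for the synthetic song-corpus generator
#'
#' Bundles every tunable of the generator with defaults that emulate a
#' territorial-song field study on a cavity-nesting passerine: each focal
#' male is exposed to a caged conspecific stimulus (male or female), then
#' recorded for 20 songs.  Songs are 3-5 s structures of roughly 0.1 s
#' syllables separated by a few seconds of silence; individual repertoires
#' hold 20-100 syllable types drawn from a global library.  Stimuli are
#' year-specific (different sets of stimulus birds are used in different
#' years) and each stimulus serves 1-15 recordings (mean about 3.33).
#'
#' The default variance components (focal male 1.798, stimulus 0.286, year
#' 0.005, residual 1.492, in squared trait units) reproduce the hierarchical
#' structure of a strongly individual-repeatable trait such as song rate;
#' the default corpus-level shifts on song length and song frequency are the
#' square roots of published variance components for those traits, so that
#' recording-level aggregates inherit a realistic stimulus/focal/year
#' decomposition.
#'
#' @param n_stimuli number of stimulus birds.
#' @param recordings_per_stimulus `NULL` (draw from a truncated geometric on
#'   1-15 with mean 3.33), a single count used for every stimulus, or a
#'   vector of counts of length `n_stimuli`.
#' @param n_years number of field seasons; stimuli are partitioned across
#'   years and never reused between years.
#' @param songs_per_recording songs analysed per recording (study standard: 20).
#' @param stimulus_sex `"M"` or `"F"`; determines whether the elapsed-time
#'   covariate exists and whether repeated focal males occur.
#' @param fixed_effects named numeric vector of fixed-effect coefficients on
#'   the simulated trait; recognised names are `intercept`, `date`, `age`
#'   (adult = 1) and `elapsed_min`.
#' @param variance_components named variances (trait units squared) of the
#'   Gaussian random intercepts; names among `stimulus`, `focal`, `year`.
#' @param residual_variance residual trait variance.
#' @param focal_repeat_prob probability that a recording reuses an already
#'   sampled focal male of the same year (how often singers repeat across
#'   stimuli is a free parameter of the design, not fixed by the emulated
#'   study).
#' @param repertoire_range integer range of per-male repertoire sizes.
#' @param n_global_types size of the global syllable-prototype library.
#' @param syllable_duration_s syllable duration in seconds.
#' @param song_length_range_s uniform range of target song lengths (s).
#' @param inter_song_gap_s uniform range of silent gaps between songs (s).
#' @param tempo_per_s baseline syllable emission rate (syllables per second
#'   of song).
#' @param proto_noise within-type feature jitter as a fraction of the
#'   between-type grid spacing; small values make syllable types separable.
#' @param length_shift_sd named SDs (s) of the song-length shifts contributed
#'   by stimulus, focal male and year; zero switches a level off.
#' @param freq_shift_sd named SDs (kHz) of the frequency shifts, same names.
#' @param stimulus_effect_songs indices of the songs affected by the stimulus
#'   shift (`NULL` = every song); restricting this to the first songs of a
#'   recording models a social effect that fades after stimulus removal.
#' @param seed integer seed; all generator functions are deterministic given
#'   the configuration.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_stimuli = 20,
                       recordings_per_stimulus = NULL,
                       n_years = 6,
                       songs_per_recording = 20,
                       stimulus_sex = c("M", "F"),
                       fixed_effects = c(intercept = 0),
                       variance_components = c(focal = 1.798,
                                               stimulus = 0.286,
                                               year = 0.005),
                       residual_variance = 1.492,
                       focal_repeat_prob = 0.15,
                       repertoire_range = c(20L, 100L),
                       n_global_types = 240L,
                       syllable_duration_s = 0.1,
                       song_length_range_s = c(3, 5),
                       inter_song_gap_s = c(2, 4),
                       tempo_per_s = 3.3,
                       proto_noise = 0.04,
                       length_shift_sd = c(stimulus = sqrt(0.031),
                                           focal = sqrt(0.046),
                                           year = sqrt(0.021)),
                       freq_shift_sd = c(stimulus = sqrt(0.019),
                                         focal = sqrt(0.048),
                                         year = 0),
                       stimulus_effect_songs = NULL,
                       seed = 1L) {
  stimulus_sex <- match.arg(stimulus_sex)
  stopifnot(n_stimuli >= 1, n_years >= 1, songs_per_recording >= 1,
            residual_variance >= 0, syllable_duration_s > 0,
            length(repertoire_range) == 2L,
            repertoire_range[1] >= 1)
  if (any(variance_components < 0))
    stop("variance components must be non-negative")
  bad <- setdiff(names(variance_components), c("stimulus", "focal", "year"))
  if (length(bad))
    stop("unknown grouping factor in 'variance_components': ",
         paste(bad, collapse = ", "))
  if (repertoire_range[2] > n_global_types)
    stop("repertoire range exceeds the global syllable library size")
  if (!is.null(recordings_per_stimulus)) {
    if (!length(recordings_per_stimulus) %in% c(1L, n_stimuli))
      stop("'recordings_per_stimulus' must be NULL, a scalar, or one count per stimulus")
    if (any(recordings_per_stimulus < 0))
      stop("recording counts must be non-negative")
  }
  structure(list(
    n_stimuli = as.integer(n_stimuli),
    recordings_per_stimulus = recordings_per_stimulus,
    n_years = as.integer(n_years),
    songs_per_recording = as.integer(songs_per_recording),
    stimulus_sex = stimulus_sex,
    fixed_effects = fixed_effects,
    variance_components = variance_components,
    residual_variance = residual_variance,
    focal_repeat_prob = focal_repeat_prob,
    repertoire_range = as.integer(repertoire_range),
    n_global_types = as.integer(n_global_types),
    syllable_duration_s = syllable_duration_s,
    song_length_range_s = song_length_range_s,
    inter_song_gap_s = inter_song_gap_s,
    tempo_per_s = tempo_per_s,
    proto_noise = proto_noise,
    length_shift_sd = length_shift_sd,
    freq_shift_sd = freq_shift_sd,
    stimulus_effect_songs = stimulus_effect_songs,
    seed = as.integer(seed)), class = "sim_config")
}

# Truncated geometric on 1..15 calibrated so the truncated mean matches the
# published stimulus-reuse mean of 3.33 (SD about 3).  Only the summary
# moments of the reuse distribution are known, so the success probability is
# solved once from the mean.
.reuse_prob <- local({
  p_cached <- NULL
  function() {
    if (is.null(p_cached)) {
      trunc_mean <- function(p) {
        k <- 1:15
        pr <- stats::dgeom(k - 1, p)
        sum(k * pr) / sum(pr)
      }
      p_cached <<- stats::uniroot(function(p) trunc_mean(p) - 3.33,
                                  c(0.05, 0.9))$root
    }
    p_cached
  }
})

.rtrunc_geom <- function(n, p) {
  k <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rgeom(1, p) + 1L
      if (x <= 15L) { k[i] <- x; break }
    }
  }
  k
}

#' Generate a recording-level experimental design
#'
#' Produces one row per song recording: which focal male was recorded, after
#' exposure to which stimulus bird, in which year, on which day of the
#' season, at what age, and (for male stimuli) how many minutes elapsed
#' between stimulus removal and recording start.  Stimuli are partitioned
#' across years — a stimulus level never spans two years — and serve a
#' variable number of recordings.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a data frame with columns `recording_id`, `focal_male_id`,
#'   `stimulus_id`, `stimulus_sex`, `year`, `date` (day of season, 1 = 11
#'   April), `focal_age` (`yearling`/`adult`) and `elapsed_min` (`NA` for
#'   female stimuli).
#' @export
simulate_design <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed %||% config$seed)

  ns <- config$n_stimuli
  counts <- config$recordings_per_stimulus
  counts <- if (is.null(counts)) .rtrunc_geom(ns, .reuse_prob())
            else rep_len(as.integer(counts), ns)
  if (sum(counts) < 1L) stop("design has zero recordings")

  years <- paste0("Y", seq_len(config$n_years))
  stim_year <- sort(rep_len(seq_len(config$n_years), ns))
  stim_id <- sprintf("stim%02d", seq_len(ns))

  rec_stim <- rep(seq_len(ns), counts)
  n_rec <- length(rec_stim)
  rec_year <- stim_year[rec_stim]

  # focal males: new bird per recording unless a same-year male is reused
  focal <- character(n_rec)
  n_male <- 0L
  by_year <- split(seq_len(n_rec), rec_year)
  for (idx in by_year) {
    seen <- character(0)
    for (i in idx) {
      if (length(seen) && stats::runif(1) < config$focal_repeat_prob) {
        focal[i] <- sample(seen, 1L)
      } else {
        n_male <- n_male + 1L
        focal[i] <- sprintf("male%03d", n_male)
        seen <- c(seen, focal[i])
      }
    }
  }

  data.frame(
    recording_id = sprintf("rec%03d", seq_len(n_rec)),
    focal_male_id = focal,
    stimulus_id = stim_id[rec_stim],
    stimulus_sex = config$stimulus_sex,
    year = factor(years[rec_year], levels = years),
    date = sample.int(27L, n_rec, replace = TRUE),
    focal_age = factor(sample(c("yearling", "adult"), n_rec, replace = TRUE),
                       levels = c("yearling", "adult")),
    elapsed_min = if (config$stimulus_sex == "M")
      round(stats::runif(n_rec, 1, 15), 1) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Simulate a recording-level trait with known variance structure
#'
#' Draws one trait value per recording as fixed part + stimulus intercept +
#' focal-male intercept + year intercept + Gaussian residual, with the
#' variances in `config$variance_components` and
#' `config$residual_variance`.  The drawn intercepts and the generating
#' variances are attached as the `"ground_truth"` attribute, enabling
#' parameter-recovery experiments against [vcmm()].
#'
#' @param design a design from [simulate_design()].
#' @param config the [sim_config()] used to build the design.
#' @param seed optional integer overriding the derived seed.
#' @return the design data frame with an added `trait` column and a
#'   `ground_truth` attribute (list of per-level intercepts and the
#'   generating variances).
#' @export
simulate_traits <- function(design, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed %||% (config$seed + 1L))

  vc <- config$variance_components
  fe <- config$fixed_effects
  n <- nrow(design)

  val <- rep(unname(fe["intercept"]) %|NA|% 0, n)
  if (!is.na(fe["date"])) val <- val + fe[["date"]] * design$date
  if (!is.na(fe["age"])) val <- val + fe[["age"]] * (design$focal_age == "adult")
  if (!is.na(fe["elapsed_min"]) && !all(is.na(design$elapsed_min)))
    val <- val + fe[["elapsed_min"]] * design$elapsed_min

  draws <- list()
  fac <- list(stimulus = factor(design$stimulus_id),
              focal = factor(design$focal_male_id),
              year = design$year)
  for (g in names(vc)) {
    f <- droplevels(fac[[g]])
    u <- stats::rnorm(nlevels(f), 0, sqrt(vc[[g]]))
    names(u) <- levels(f)
    draws[[g]] <- u
    val <- val + u[as.integer(f)]
  }
  val <- val + stats::rnorm(n, 0, sqrt(config$residual_variance))

  out <- design
  out$trait <- unname(val)
  attr(out, "ground_truth") <- list(
    intercepts = draws,
    variances = as.list(vc),
    residual_variance = config$residual_variance,
    fixed_effects = as.list(fe))
  out
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Simulate a syllable-level song corpus
#'
#' Builds a full synthetic corpus: a global library of syllable prototypes on
#' a jittered grid in 5-D feature space (duration, minimum/maximum/mean
#' frequency, bandwidth), a repertoire per focal male, and for every
#' recording the configured number of songs, each a timed sequence of
#' repertoire syllables.  Stimulus, focal-male and year effects enter as
#' Gaussian shifts on song length and on syllable frequencies
#' (`length_shift_sd`, `freq_shift_sd`), so recording-level trait aggregates
#' inherit the hierarchical variance structure.  When
#' `stimulus_effect_songs` is set, the stimulus shift applies only to those
#' songs — a social effect that fades after stimulus removal.
#'
#' @param design a design from [simulate_design()].
#' @param config the corresponding [sim_config()].
#' @param seed optional integer overriding the derived seed.
#' @return a data frame of syllable segments with columns `recording_id`,
#'   `song_index`, `syllable_index`, `onset_s`, `offset_s`, `f_min_kHz`,
#'   `f_max_kHz`, `f_mean_kHz` and the generating prototype id `type_true`;
#'   ground truth (prototype library, per-male repertoires and sizes, shift
#'   draws) in the `"ground_truth"` attribute.
#' @export
simulate_corpus <- function(design, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed %||% (config$seed + 2L))

  proto <- .syllable_library(config)
  males <- unique(design$focal_male_id)
  rep_size <- stats::setNames(
    sample(seq(config$repertoire_range[1], config$repertoire_range[2]),
           length(males), replace = TRUE), males)
  if (any(rep_size > nrow(proto)))
    stop("repertoire size exceeds the syllable library size")
  repertoire <- lapply(males, function(m)
    sample.int(nrow(proto), rep_size[[m]]))
  names(repertoire) <- males

  shift <- function(sds, fac) {
    lapply(stats::setNames(names(sds), names(sds)), function(g) {
      f <- droplevels(factor(fac[[g]]))
      stats::setNames(stats::rnorm(nlevels(f), 0, sds[[g]]), levels(f))
    })
  }
  fac <- list(stimulus = design$stimulus_id, focal = design$focal_male_id,
              year = design$year)
  len_shift <- shift(config$length_shift_sd, fac)
  frq_shift <- shift(config$freq_shift_sd, fac)

  eff_songs <- config$stimulus_effect_songs %||%
    seq_len(config$songs_per_recording)
  dur <- config$syllable_duration_s
  rows <- vector("list", nrow(design))

  for (r in seq_len(nrow(design))) {
    rec <- design[r, ]
    base_len <- len_shift$focal[rec$focal_male_id] %|NA|% 0 +
      (len_shift$year[as.character(rec$year)] %|NA|% 0)
    base_frq <- frq_shift$focal[rec$focal_male_id] %|NA|% 0 +
      (frq_shift$year[as.character(rec$year)] %|NA|% 0)
    stim_len <- len_shift$stimulus[rec$stimulus_id] %|NA|% 0
    stim_frq <- frq_shift$stimulus[rec$stimulus_id] %|NA|% 0
    reps <- repertoire[[rec$focal_male_id]]

    t0 <- 0
    songs <- vector("list", config$songs_per_recording)
    for (s in seq_len(config$songs_per_recording)) {
      in_eff <- s %in% eff_songs
      L <- stats::runif(1, config$song_length_range_s[1],
                        config$song_length_range_s[2]) +
        base_len + if (in_eff) stim_len else 0
      L <- max(L, 3 * dur)
      nsyl <- max(2L, round(config$tempo_per_s * L))
      types <- reps[sample.int(length(reps), nsyl, replace = TRUE)]
      feat <- .jitter_features(proto[types, , drop = FALSE],
                               config$proto_noise)
      # space syllables so the song spans exactly L (first onset to last offset)
      gap <- max(0.01, (L - sum(feat$duration)) / (nsyl - 1L))
      onset <- t0 + cumsum(c(0, feat$duration[-nsyl] + gap))
      fshift <- base_frq + if (in_eff) stim_frq else 0
      songs[[s]] <- data.frame(
        recording_id = rec$recording_id, song_index = s,
        syllable_index = seq_len(nsyl),
        onset_s = onset, offset_s = onset + feat$duration,
        f_min_kHz = feat$f_min + fshift,
        f_max_kHz = feat$f_max + fshift,
        f_mean_kHz = feat$f_mean + fshift,
        type_true = types, stringsAsFactors = FALSE)
      t0 <- t0 + L + stats::runif(1, config$inter_song_gap_s[1],
                                  config$inter_song_gap_s[2])
    }
    rows[[r]] <- do.call(rbind, songs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(
    prototypes = proto,
    repertoire = repertoire,
    repertoire_size = rep_size,
    length_shifts = len_shift,
    freq_shifts = frq_shift)
  out
}

# Global syllable library: prototypes on a jittered grid in
# (duration, mean frequency, bandwidth); min/max frequency derived so that
# f_max >= f_mean >= f_min always holds.  Grid placement keeps between-type
# distances controllable relative to the within-type jitter.
.syllable_library <- function(config) {
  n <- config$n_global_types
  dims <- c(8L, 6L, 5L)
  while (prod(dims) < n) dims[1] <- dims[1] + 1L
  g <- expand.grid(d = seq_len(dims[1]), f = seq_len(dims[2]),
                   b = seq_len(dims[3]))
  g <- g[seq_len(n), ]
  duration <- 0.06 + (g$d - 1) / (dims[1] - 1) * 0.08
  f_mean <- 2.5 + (g$f - 1) / (dims[2] - 1) * 4.5
  bw <- 0.4 + (g$b - 1) / (dims[3] - 1) * 2.0
  # fixed small jitter de-aligns the grid without shrinking separations
  duration <- duration + stats::runif(n, -0.002, 0.002)
  f_mean <- f_mean + stats::runif(n, -0.05, 0.05)
  bw <- bw + stats::runif(n, -0.02, 0.02)
  data.frame(type = seq_len(n), duration_s = duration,
             f_min = f_mean - bw / 2, f_max = f_mean + bw / 2,
             f_mean = f_mean)
}

# Within-type rendition noise, scaled to the grid spacing of each feature.
.jitter_features <- function(proto, noise) {
  n <- nrow(proto)
  f_mean <- proto$f_mean + stats::rnorm(n, 0, noise * 0.9)
  half_bw <- (proto$f_max - proto$f_min) / 2 *
    exp(stats::rnorm(n, 0, noise))
  list(f_min = f_mean - half_bw, f_max = f_mean + half_bw, f_mean = f_mean,
       duration = pmax(0.02, proto$duration_s + stats::rnorm(n, 0, noise * 0.016)))
}

#' Write a syllable segment table (and its ground truth) to disk
#'
#' Segments go to a UTF-8 tab-separated file; when present, the
#' `ground_truth` attribute is written alongside as JSON
#' (`<path>.ground_truth.json`).
#'
#' @param segments a segment table from [simulate_corpus()] or read back by
#'   [read_segments()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  gt <- attr(segments, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, paste0(path, ".ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
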