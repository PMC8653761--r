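#' Song-level traits from syllable segments
#'
#' Computes the trait set of one song from its measured syllables: song
#' length (first onset to last offset), tempo (syllables per second of
#' song), short-term complexity (distinct syllable types / total syllables),
#' and the frequency statistics of the song — minimum, maximum, mean and
#' bandwidth — all taken over the syllables' mean frequencies.
#'
#' @param segments data frame of the syllables of a single song, with
#'   columns `onset_s`, `offset_s`, `f_mean_kHz` and (for complexity) a
#'   syllable-type label column.
#' @param complexity logical; compute complexity (requires labels)?
#' @param label_col name of the type-label column.
#' @return one-row data frame: `song_length_s`, `tempo_per_s`, `complexity`,
#'   `f_min_kHz`, `f_max_kHz`, `f_mean_kHz`, `bandwidth_kHz`.
#' @export
song_traits <- function(segments, complexity = TRUE,
                        label_col = "type_label") {
  if (nrow(segments) < 1L) stop("song has no syllables")
  if (any(segments$offset_s <= segments$onset_s))
    stop("invalid segment: offset must exceed onset")
  n <- nrow(segments)
  len <- max(segments$offset_s) - min(segments$onset_s)
  fm <- segments$f_mean_kHz
  cx <- NA_real_
  if (complexity) {
    lab <- segments[[label_col]]
    if (is.null(lab) || anyNA(lab))
      stop("complexity requested but syllable type labels are missing")
    cx <- length(unique(lab)) / n
  }
  data.frame(song_length_s = len, tempo_per_s = n / len, complexity = cx,
             f_min_kHz = min(fm), f_max_kHz = max(fm), f_mean_kHz = mean(fm),
             bandwidth_kHz = max(fm) - min(fm))
}

#' Recording-level traits: means over songs, song rate, repertoire count
#'
#' Averages every song-level trait over the songs of one recording and adds
#' the two traits defined only at recording level: song rate (60 divided by
#' the median inter-song interval) and, when type labels are present, the
#' number of distinct syllable types used in the recording.
#'
#' The recording standard of the emulated protocol is 20 songs; a different
#' count triggers a warning, not an error.  Song "interval" is the
#' start-to-start spacing of consecutive songs by default, which makes song
#' rate an actual songs-per-minute; `interval = "gap"` uses the silent gap
#' (start minus previous end) instead.
#'
#' @param segments syllable table of one recording (`song_index` orders the
#'   songs).
#' @param complexity,label_col passed to [song_traits()].
#' @param expect_songs expected number of songs (warn when different).
#' @param interval `"start"` (start-to-start, default) or `"gap"`.
#' @return one-row data frame of trait means plus `song_rate_per_min` and
#'   `repertoire_size` (`NA` when labels are absent); song rate is `NA` with
#'   fewer than two songs.
#' @export
recording_traits <- function(segments, complexity = TRUE,
                             label_col = "type_label",
                             expect_songs = 20L,
                             interval = c("start", "gap")) {
  interval <- match.arg(interval)
  songs <- split(segments, segments$song_index)
  if (length(songs) != expect_songs)
    warning(sprintf("recording has %d songs (expected %d)",
                    length(songs), expect_songs))
  per_song <- do.call(rbind, lapply(songs, song_traits,
                                    complexity = complexity,
                                    label_col = label_col))
  out <- as.data.frame(lapply(per_song, mean))

  starts <- vapply(songs, function(s) min(s$onset_s), numeric(1))
  ends <- vapply(songs, function(s) max(s$offset_s), numeric(1))
  ord <- order(starts)
  out$song_rate_per_min <- if (length(songs) < 2L) NA_real_ else {
    iv <- if (interval == "start") diff(starts[ord])
          else starts[ord][-1] - ends[ord][-length(ord)]
    60 / stats::median(iv)
  }
  out$repertoire_size <-
    if (complexity && !is.null(segments[[label_col]]))
      length(unique(segments[[label_col]]))
    else NA_integer_
  out
}

#' Recording-level trait table for a whole corpus
#'
#' Applies [recording_traits()] to every recording of a syllable corpus.
#'
#' @param segments corpus syllable table (column `recording_id` groups
#'   recordings).
#' @param ... passed to [recording_traits()].
#' @return data frame with one row per recording, `recording_id` first.
#' @export
corpus_traits <- function(segments, ...) {
  recs <- split(segments, segments$recording_id)
  out <- do.call(rbind, lapply(recs, recording_traits, ...))
  cbind(data.frame(recording_id = names(recs), stringsAsFactors = FALSE),
        out, row.names = NULL)
}

#' Cluster syllables into types by k-means
#'
#' Pools all syllables of a corpus, z-scores the five spectrographic
#' features (duration, minimum/maximum/mean frequency, bandwidth) and
#' partitions them into `k` syllable types with [stats::kmeans()] (fixed
#' internal seed, 10 restarts, Lloyd-compatible guards for degenerate
#' input).  `k` is lowered to the number of distinct feature points when
#' necessary, with a message.
#'
#' @param segments corpus syllable table with columns `onset_s`, `offset_s`,
#'   `f_min_kHz`, `f_max_kHz`, `f_mean_kHz`.
#' @param k target number of syllable types (study standard: 200).
#' @param nstart k-means restarts.
#' @param seed internal clustering seed (the caller's RNG is untouched).
#' @return `segments` with a `type_label` column of cluster indices.
#' @export
syllable_types <- function(segments, k = 200L, nstart = 10L, seed = 1L) {
  if (nrow(segments) == 0L) stop("empty corpus: no syllables to cluster")
  feats <- cbind(duration = segments$offset_s - segments$onset_s,
                 f_min = segments$f_min_kHz, f_max = segments$f_max_kHz,
                 f_mean = segments$f_mean_kHz,
                 bandwidth = segments$f_max_kHz - segments$f_min_kHz)
  if (any(!is.finite(feats))) stop("non-finite syllable features")
  sds <- apply(feats, 2, stats::sd)
  # features that are constant up to floating-point residue must not be
  # blown up by the z-scoring
  tiny <- sds <= 1e-8 * pmax(abs(colMeans(feats)), 1)
  z <- scale(feats, scale = ifelse(tiny, 1, sds))
  z[, tiny] <- 0
  # distinct up to floating-point residue (e.g. (a+b)-a != b)
  first_uniq <- !duplicated(round(z, 8))
  n_distinct <- sum(first_uniq)
  degenerate <- n_distinct <= k
  if (n_distinct < k) {
    message(sprintf("only %d distinct feature points; lowering k from %d",
                    n_distinct, k))
    k <- n_distinct
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  km <- if (k == 1L) list(cluster = rep(1L, nrow(z)))
        else if (degenerate)
          # one cluster per distinct point is the exact optimum here
          stats::kmeans(z, centers = z[first_uniq, , drop = FALSE],
                        iter.max = 100L)
        else stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  segments$type_label <- as.integer(km$cluster)
  segments
}

#' Estimate per-recording repertoire size
#'
#' The repertoire of a recording is the number of distinct k-means syllable
#' types detected among its syllables — the cluster-based surrogate for a
#' manual enumeration of types.  Clustering is global across the pooled
#' corpus (see [syllable_types()]); existing `type_label` values are reused
#' when present so that complexity and repertoire share one type system.
#'
#' @param segments corpus syllable table.
#' @param k,nstart,seed passed to [syllable_types()] when labels are absent.
#' @return data frame `recording_id`, `repertoire`; the labelled segment
#'   table is attached as attribute `"segments"`.
#' @export
estimate_repertoire <- function(segments, k = 200L, nstart = 10L, seed = 1L) {
  if (is.null(segments$type_label) || anyNA(segments$type_label))
    segments <- syllable_types(segments, k = k, nstart = nstart, seed = seed)
  counts <- tapply(segments$type_label, segments$recording_id,
                   function(x) length(unique(x)))
  out <- data.frame(recording_id = names(counts),
                    repertoire = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "segments") <- segments
  out
}
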