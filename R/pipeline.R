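#' Body-condition index as mass-on-tarsus residuals
#'
#' Condition is the residual of a body-mass on tarsus-length regression,
#' built separately for each sex, with year as a random intercept to absorb
#' season-specific effects.  With a single year level the model collapses to
#' an ordinary regression (reported with a message).
#'
#' @param mass body mass, g.
#' @param tarsus tarsus length, mm.
#' @param sex factor/character, one entry per bird.
#' @param year year of measurement, one entry per bird.
#' @return numeric vector of condition residuals, aligned with the input.
#' @export
condition_index <- function(mass, tarsus, sex, year) {
  stopifnot(length(mass) == length(tarsus), length(mass) == length(sex),
            length(mass) == length(year))
  out <- rep(NA_real_, length(mass))
  for (s in unique(sex)) {
    i <- which(sex == s)
    if (length(i) < 3L)
      stop(sprintf("need at least 3 birds of sex '%s' for the condition regression", s))
    d <- data.frame(mass = mass[i], tarsus = tarsus[i],
                    year = factor(year[i]))
    if (nlevels(d$year) >= 2L) {
      fit <- vcmm(mass ~ tarsus + (1 | year), d)
      out[i] <- stats::residuals(fit)
    } else {
      message(sprintf("single year for sex '%s': plain regression used", s))
      out[i] <- stats::residuals(stats::lm(mass ~ tarsus, d))
    }
  }
  out
}

# model structure of the two experiments; elapsed time and the focal-male
# random term exist only in the male-stimulus data
.experiment_formula <- function(trait, sex) {
  rhs <- if (sex == "M")
    "date + focal_age + elapsed_min + (1 | focal_male_id) + (1 | stimulus_id:year) + (1 | year)"
  else
    "date + focal_age + (1 | stimulus_id:year) + (1 | year)"
  stats::as.formula(paste(trait, "~", rhs))
}

.default_traits <- c("song_length_s", "f_mean_kHz", "f_min_kHz", "f_max_kHz",
                     "bandwidth_kHz", "tempo_per_s", "complexity",
                     "repertoire_size", "song_rate_per_min")

.check_experiment_data <- function(data, sex) {
  need <- c("date", "focal_age", "stimulus_id", "year")
  if (sex == "M") need <- c(need, "elapsed_min", "focal_male_id")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("missing covariate column(s): ", paste(missing, collapse = ", "))
  if (sex == "M" && all(is.na(data$elapsed_min)))
    stop("missing covariate: 'elapsed_min' has no data")
  invisible(TRUE)
}

#' Run a stimulus-identity variance-partitioning experiment
#'
#' For every song trait, fits the study's mixed model by ML — fixed effects:
#' recording date and focal age (plus, for male stimuli, minutes elapsed
#' between stimulus removal and recording); random intercepts: stimulus
#' identity nested in year, year, and (male stimuli) the focal male — then
#' decomposes the phenotypic variance and attaches parametric-bootstrap CIs
#' and signed Cramer's V effect sizes for the fixed terms.
#'
#' @param traits recording-level trait table (see [corpus_traits()]),
#'   `recording_id` column required.
#' @param meta recording metadata with `recording_id`, `stimulus_id`,
#'   `stimulus_sex`, `year`, `date`, `focal_age` and, for male stimuli,
#'   `focal_male_id` and `elapsed_min`.
#' @param trait_cols trait columns to analyse; defaults to the nine study
#'   traits present in `traits`.
#' @param B bootstrap replicates for variance-component CIs (0 skips CIs).
#' @param effect_B bootstrap replicates for effect-size CIs (default 0:
#'   point estimates only).
#' @param seed integer seed driving all bootstrap resampling.
#' @return an object of class `"sv_experiment"`: per-trait list of `fit`,
#'   `varpart`, `boot`, `effects`, plus `sex` and `n_used` bookkeeping.
#' @export
run_experiment <- function(traits, meta, trait_cols = NULL, B = 1000L,
                           effect_B = 0L, seed = NULL) {
  sex <- unique(as.character(meta$stimulus_sex))
  if (length(sex) != 1L)
    stop("metadata mixes stimulus sexes; analyse the two experiments separately")
  data <- merge(meta, traits, by = "recording_id")
  .check_experiment_data(data, sex)
  if (sex == "M" && !any(duplicated(data$focal_male_id)))
    warning("no repeated focal males: the focal-male variance is not identifiable")
  trait_cols <- trait_cols %||% intersect(.default_traits, names(traits))
  if (!length(trait_cols)) stop("no trait columns found")

  results <- list()
  for (tr in trait_cols) {
    if (!tr %in% names(data)) next
    if (all(is.na(data[[tr]]))) {
      message(sprintf("trait '%s' has no data; skipped", tr))
      next
    }
    fml <- .experiment_formula(tr, sex)
    fit <- vcmm(fml, data)
    vp <- varpart(fit)
    bt <- if (B > 0L)
      vc_bootstrap(fit, B = B, seed = if (is.null(seed)) NULL
                   else seed + match(tr, trait_cols))
    else NULL
    terms_fixed <- attr(fit$terms, "term.labels")
    effs <- lapply(terms_fixed, function(tm)
      cramers_v(fit, tm, B = effect_B,
                seed = if (is.null(seed)) NULL
                       else seed + 1000L + match(tr, trait_cols)))
    names(effs) <- terms_fixed
    results[[tr]] <- list(trait = tr, fit = fit, varpart = vp, boot = bt,
                          effects = effs, n_used = fit$n)
  }
  structure(list(sex = sex, results = results, B = B),
            class = "sv_experiment")
}

#' @rdname run_experiment
#' @export
run_female_experiment <- function(traits, meta, ...) {
  if (!all(meta$stimulus_sex == "F"))
    stop("female experiment requires stimulus_sex == 'F' rows only")
  run_experiment(traits, meta, ...)
}

#' @rdname run_experiment
#' @export
run_male_experiment <- function(traits, meta, ...) {
  if (!all(meta$stimulus_sex == "M"))
    stop("male experiment requires stimulus_sex == 'M' rows only")
  run_experiment(traits, meta, ...)
}

#' @export
print.sv_experiment <- function(x, ...) {
  cat(sprintf("Stimulus-identity experiment (%s stimuli), %d trait(s)\n\n",
              if (x$sex == "M") "male" else "female", length(x$results)))
  print(report_table(x), digits = 4)
  invisible(x)
}

#' Stimulus-effect trajectory across temporal song bins
#'
#' Splits each recording's songs, in their original order, into consecutive
#' bins of `bin_size` songs (songs 1-5, 6-10, ...), averages one song-level
#' trait per bin, refits the experiment's mixed model on every bin, and
#' tracks the percentage of variance explained by stimulus identity with a
#' parametric-bootstrap CI.  A declining percentage across bins indicates a
#' social effect that fades after the stimulus is removed.  Song rate and
#' repertoire size are defined only at the 20-song level and are not
#' valid bin traits.
#'
#' @param segments corpus syllable table.
#' @param meta recording metadata (see [run_experiment()]).
#' @param trait song-level trait name (one of `song_length_s`,
#'   `tempo_per_s`, `complexity`, `f_min_kHz`, `f_max_kHz`, `f_mean_kHz`,
#'   `bandwidth_kHz`).
#' @param bin_size songs per bin.
#' @param B bootstrap replicates per bin.
#' @param seed integer seed.
#' @return an object of class `"sv_bins"`: data frame `series` (bin, trait
#'   mean, stimulus variance and percent with CI) and the per-bin fits.
#' @export
temporal_bin_analysis <- function(segments, meta, trait, bin_size = 5L,
                                  B = 200L, seed = NULL) {
  ok <- c("song_length_s", "tempo_per_s", "complexity", "f_min_kHz",
          "f_max_kHz", "f_mean_kHz", "bandwidth_kHz")
  if (!trait %in% ok)
    stop(sprintf("'%s' is not a song-level trait; bins support: %s",
                 trait, paste(ok, collapse = ", ")))
  need_labels <- trait == "complexity"
  if (need_labels &&
      (is.null(segments$type_label) || anyNA(segments$type_label)))
    segments <- syllable_types(segments)

  sex <- unique(as.character(meta$stimulus_sex))
  if (length(sex) != 1L) stop("metadata mixes stimulus sexes")

  per_song <- do.call(rbind, lapply(
    split(segments, list(segments$recording_id, segments$song_index),
          drop = TRUE),
    function(s) cbind(data.frame(recording_id = s$recording_id[1],
                                 song_index = s$song_index[1]),
                      song_traits(s, complexity = need_labels))))
  per_song$bin <- ceiling(per_song$song_index / bin_size)

  # drop incomplete trailing bins
  cnt <- stats::aggregate(song_index ~ recording_id + bin, per_song, length)
  bad <- cnt[cnt$song_index < bin_size, ]
  if (nrow(bad) > 0L) {
    message(sprintf("dropping %d incomplete bin(s) from recordings with fewer songs",
                    nrow(bad)))
    per_song <- per_song[!paste(per_song$recording_id, per_song$bin) %in%
                           paste(bad$recording_id, bad$bin), ]
  }

  agg <- stats::aggregate(per_song[[trait]],
                          by = list(recording_id = per_song$recording_id,
                                    bin = per_song$bin), FUN = mean)
  names(agg)[3] <- trait

  bins <- sort(unique(agg$bin))
  fits <- list(); series <- list()
  for (b in bins) {
    d <- merge(meta, agg[agg$bin == b, c("recording_id", trait)],
               by = "recording_id")
    fit <- vcmm(.experiment_formula(trait, sex), d)
    vp <- varpart(fit)
    stim_row <- grep("^stimulus_id", vp$component)
    bt <- if (B > 0L)
      vc_bootstrap(fit, B = B, seed = if (is.null(seed)) NULL else seed + b)
    else NULL
    series[[length(series) + 1L]] <- data.frame(
      bin = b, n = fit$n, trait_mean = mean(d[[trait]], na.rm = TRUE),
      stimulus_variance = vp$variance[stim_row],
      stimulus_pct = vp$percent[stim_row],
      pct_lwr = if (is.null(bt)) NA_real_ else bt$ci_percent[1, stim_row],
      pct_upr = if (is.null(bt)) NA_real_ else bt$ci_percent[2, stim_row])
    fits[[length(fits) + 1L]] <- fit
  }
  structure(list(trait = trait, series = do.call(rbind, series),
                 fits = fits, bin_size = bin_size, sex = sex),
            class = "sv_bins")
}

#' @export
print.sv_bins <- function(x, digits = 4, ...) {
  cat(sprintf("Stimulus-variance trajectory for '%s' over bins of %d songs\n",
              x$trait, x$bin_size))
  print(x$series, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sv_bins <- function(x, ...) {
  s <- x$series
  ylim <- c(0, max(s$pct_upr, s$stimulus_pct, na.rm = TRUE) * 1.05)
  bp <- graphics::barplot(s$stimulus_pct, names.arg = s$bin,
                          xlab = "Song bin (5 consecutive songs)",
                          ylab = "Stimulus-identity variance (%)",
                          ylim = ylim, ...)
  if (!all(is.na(s$pct_lwr)))
    graphics::arrows(bp, s$pct_lwr, bp, s$pct_upr, angle = 90, code = 3,
                     length = 0.05)
  invisible(x)
}

#' Explain the among-stimulus variance with stimulus phenotypes
#'
#' Refits a trait's experiment model after adding standardized stimulus
#' phenotypes (tarsus length, body condition, wing patch size, days in
#' captivity and — male stimuli only — forehead patch size) to the fixed
#' part, and reports how the percentage of variance attributed to stimulus
#' identity changes, together with a signed Cramer's V per phenotype term.
#' A drop toward zero indicates that the measured phenotypes carry the cues
#' behind the stimulus-specific song adjustment.
#'
#' @param traits,meta as in [run_experiment()].
#' @param phenotypes stimulus phenotype table: `stimulus_id`, `tarsus_mm`,
#'   `body_mass_g`, `wing_patch_mm`, `captivity_days` and, for male stimuli,
#'   `forehead_patch_mm2`.
#' @param trait_cols trait columns to analyse.
#' @param phenotype_terms phenotype predictors to include; default depends
#'   on stimulus sex.  Requesting forehead patch for female stimuli is an
#'   error (females lack the patch).
#' @param B bootstrap replicates for the phenotype effect-size CIs.
#' @param seed integer seed.
#' @return an object of class `"sv_phenofit"`: per trait, stimulus-variance
#'   percent before/after phenotype inclusion and per-term effect sizes.
#' @export
stimulus_trait_models <- function(traits, meta, phenotypes,
                                  trait_cols = NULL, phenotype_terms = NULL,
                                  B = 0L, seed = NULL) {
  sex <- unique(as.character(meta$stimulus_sex))
  if (length(sex) != 1L) stop("metadata mixes stimulus sexes")
  default_terms <- c("tarsus", "condition", "wing_patch", "captivity",
                     if (sex == "M") "forehead_patch")
  phenotype_terms <- phenotype_terms %||% default_terms
  if (sex == "F" && "forehead_patch" %in% phenotype_terms)
    stop("forehead patch size is undefined for female stimuli")

  stim_year <- unique(meta[, c("stimulus_id", "year")])
  ph <- merge(phenotypes, stim_year, by = "stimulus_id")
  if (anyNA(ph[, c("tarsus_mm", "body_mass_g")]))
    stop("phenotype table incomplete for the stimuli used")
  ph$condition <- condition_index(ph$body_mass_g, ph$tarsus_mm,
                                  rep(sex, nrow(ph)), ph$year)
  raw <- data.frame(stimulus_id = ph$stimulus_id,
                    tarsus = ph$tarsus_mm,
                    condition = ph$condition,
                    wing_patch = ph$wing_patch_mm,
                    captivity = ph$captivity_days)
  if (sex == "M") raw$forehead_patch <- ph$forehead_patch_mm2
  for (v in setdiff(names(raw), "stimulus_id"))
    raw[[v]] <- as.numeric(scale(raw[[v]]))   # z-transform within dataset

  data <- merge(merge(meta, traits, by = "recording_id"), raw,
                by = "stimulus_id")
  .check_experiment_data(data, sex)
  trait_cols <- trait_cols %||% intersect(.default_traits, names(traits))

  results <- list()
  for (tr in trait_cols) {
    if (!tr %in% names(data) || all(is.na(data[[tr]]))) next
    base <- vcmm(.experiment_formula(tr, sex), data)
    ext_fml <- stats::update.formula(
      .experiment_formula(tr, sex),
      paste("~ . +", paste(phenotype_terms, collapse = " + ")))
    ext <- vcmm(ext_fml, data)
    vp0 <- varpart(base); vp1 <- varpart(ext)
    stim0 <- grep("^stimulus_id", vp0$component)
    stim1 <- grep("^stimulus_id", vp1$component)
    effs <- lapply(phenotype_terms, function(tm)
      cramers_v(ext, tm, B = B,
                seed = if (is.null(seed)) NULL
                       else seed + match(tm, phenotype_terms)))
    names(effs) <- phenotype_terms
    results[[tr]] <- list(trait = tr,
                          pct_before = vp0$percent[stim0],
                          pct_after = vp1$percent[stim1],
                          fit_base = base, fit_extended = ext,
                          effects = effs)
  }
  structure(list(sex = sex, results = results, terms = phenotype_terms),
            class = "sv_phenofit")
}

#' @export
print.sv_phenofit <- function(x, digits = 3, ...) {
  cat("Stimulus-phenotype models: among-stimulus variance before/after\n")
  for (r in x$results) {
    cat(sprintf("  %-18s %6.2f%% -> %6.2f%%   V: %s\n", r$trait,
                r$pct_before, r$pct_after,
                paste(sprintf("%s %+.*f", names(r$effects),
                              digits,
                              vapply(r$effects, function(e)
                                if (e$signed) e$signed_V else e$V,
                                numeric(1))), collapse = ", ")))
  }
  invisible(x)
}

#' Publication-style results table for an experiment
#'
#' Flattens an [run_experiment()] result into one row per trait: signed
#' Cramer's V per fixed term (with bootstrap CI when available) and, per
#' random component, the variance, its CI and its percentage of the total.
#'
#' @param x an `"sv_experiment"`.
#' @return a data frame; numeric percent columns of each row sum to 100.
#' @export
report_table <- function(x) {
  stopifnot(inherits(x, "sv_experiment"))
  rows <- lapply(x$results, function(r) {
    out <- data.frame(trait = r$trait, n = r$n_used)
    for (tm in names(r$effects)) {
      e <- r$effects[[tm]]
      v <- if (e$signed) e$signed_V else e$V
      out[[paste0("V_", tm)]] <- v
      if (!is.null(e$ci)) {
        out[[paste0("V_", tm, "_lwr")]] <- e$ci[1]
        out[[paste0("V_", tm, "_upr")]] <- e$ci[2]
      }
    }
    vp <- r$varpart
    for (i in seq_len(nrow(vp))) {
      comp <- gsub("[^A-Za-z0-9]+", "_", vp$component[i])
      out[[paste0("var_", comp)]] <- vp$variance[i]
      if (!is.null(r$boot)) {
        out[[paste0("var_", comp, "_lwr")]] <- r$boot$ci_variance[1, i]
        out[[paste0("var_", comp, "_upr")]] <- r$boot$ci_variance[2, i]
      }
      out[[paste0("pct_", comp)]] <- vp$percent[i]
    }
    out
  })
  if (!length(rows)) {
    return(data.frame(trait = character(0), n = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a results table as TSV
#'
#' @param x a data frame (e.g. from [report_table()]) or an
#'   `"sv_experiment"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "sv_experiment")) x <- report_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
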