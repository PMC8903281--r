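# Scoring of perception responses and production tap records.
#
# Production scores are all dimensionless, normalised by the mean IBI of the
# excerpt's beat grid:
#   asynchrony = mean |tap - nearest beat| / mean IBI        (phase matching)
#   CDEV       = mean |IRI_i - mean IBI| / mean IBI          (tempo matching)
#   CoV        = SD(IRI) / mean(IRI)                         (variability)
# where IRI_i are the inter-response (inter-tap) intervals.

#' Percent of correct perception judgments
#'
#' @param judgment Character or factor vector of responses, `"on"`/`"off"`
#'   (any two-level coding comparable with `truth` works).
#' @param truth Vector of the true labels, same length and coding.
#' @return Percentage correct in `[0, 100]`.
#' @export
#' @examples
#' percent_correct(c("on", "off", "on"), c("on", "off", "off"))
percent_correct <- function(judgment, truth) {
  if (length(judgment) == 0) {
    stop("`judgment` must be non-empty", call. = FALSE)
  }
  if (length(judgment) != length(truth)) {
    stop("`judgment` and `truth` must have the same length", call. = FALSE)
  }
  100 * mean(as.character(judgment) == as.character(truth))
}

#' Match each tap to its nearest beat
#'
#' Pairs every tap with the beat minimising the absolute time difference.
#' A tap exactly midway between two beats is assigned to the earlier beat;
#' beats may be matched by several taps; taps before the first or after the
#' last beat match the terminal beat (no truncation window).
#'
#' @param taps Numeric vector of tap onset times, seconds.
#' @param beats Numeric vector of beat onset times, seconds, sorted
#'   increasing.
#' @return A tibble with columns `tap`, `beat_index`, `beat`, `abs_diff`.
#' @export
#' @examples
#' match_taps_to_beats(c(0.1, 0.25), c(0, 0.5, 1))
match_taps_to_beats <- function(taps, beats) {
  idx <- nearest_beat_index(taps, beats)
  tibble::tibble(tap = as.numeric(taps), beat_index = idx,
                 beat = beats[idx], abs_diff = abs(taps - beats[idx]))
}

# index of the nearest beat for each tap (tie -> earlier beat); plain
# integer vector, used on the scoring hot path
nearest_beat_index <- function(taps, beats) {
  if (length(taps) == 0 || length(beats) == 0) {
    stop("`taps` and `beats` must be non-empty", call. = FALSE)
  }
  if (is.unsorted(beats, strictly = TRUE)) {
    stop("`beats` must be strictly increasing", call. = FALSE)
  }
  if (length(beats) == 1) return(rep(1L, length(taps)))
  # midpoints between consecutive beats; left-open intervals put a tap
  # exactly at a midpoint with the earlier beat
  mids <- (beats[-1] + beats[-length(beats)]) / 2
  findInterval(taps, mids, left.open = TRUE) + 1L
}

resolve_beats <- function(grid) {
  if (inherits(grid, "bat_grid")) grid$beat_onsets else as.numeric(grid)
}

resolve_mibi <- function(grid) {
  if (inherits(grid, "bat_grid")) mean_ibi(grid)
  else mean(diff(as.numeric(grid)))
}

#' Asynchrony (phase-matching) score of one tapping trial
#'
#' Mean absolute difference between each tap and its nearest beat, divided
#' by the mean inter-beat interval. Zero means every tap landed exactly on
#' a beat; high values indicate tapping too early or too late relative to
#' the beat.
#'
#' @param taps Numeric vector of tap onsets in seconds (any order; sorted
#'   internally).
#' @param grid A `bat_grid`, or a numeric vector of beat onsets.
#' @return Dimensionless non-negative score.
#' @export
#' @examples
#' g <- make_beat_grid(120, 5)
#' asynchrony_score(g$beat_onsets + 0.05, g)  # 0.05 / 0.5 = 0.1
asynchrony_score <- function(taps, grid) {
  beats <- resolve_beats(grid)
  taps <- sort(as.numeric(taps))
  idx <- nearest_beat_index(taps, beats)
  mean(abs(taps - beats[idx])) / resolve_mibi(grid)
}

#' Coefficient of deviation (tempo-matching) score of one tapping trial
#'
#' Measures how far the produced tapping tempo deviates from the stimulus
#' tempo. The default per-interval variant averages the absolute deviation
#' of each inter-response interval (IRI) from the mean IBI, normalised by
#' the mean IBI; for steady tapping at a scaled period it equals the
#' fractional tempo error. The `"aggregate"` variant compares only the mean
#' IRI with the mean IBI, so alternating fast/slow intervals can cancel.
#'
#' @inheritParams asynchrony_score
#' @param variant `"per-interval"` (default) or `"aggregate"`.
#' @return Dimensionless non-negative score; requires at least 2 taps.
#' @export
#' @examples
#' g <- make_beat_grid(120, 6)
#' cdev_score(g$beat_onsets * 1.02 , make_beat_grid(120, 6))
cdev_score <- function(taps, grid, variant = c("per-interval", "aggregate")) {
  variant <- match.arg(variant)
  taps <- sort(as.numeric(taps))
  if (length(taps) < 2) {
    stop("CDEV requires at least 2 taps (1 inter-response interval)",
         call. = FALSE)
  }
  iri <- diff(taps)
  mibi <- resolve_mibi(grid)
  if (variant == "per-interval") {
    mean(abs(iri - mibi)) / mibi
  } else {
    abs(mean(iri) - mibi) / mibi
  }
}

#' Coefficient of variation (tapping variability) score of one trial
#'
#' SD of the inter-response intervals over their mean (sample SD, n - 1
#' denominator). Stimulus-independent: it does not reference the beat grid
#' and is invariant to uniform time rescaling.
#'
#' @inheritParams asynchrony_score
#' @return Dimensionless non-negative score; requires at least 3 taps.
#' @export
cov_score <- function(taps) {
  taps <- sort(as.numeric(taps))
  if (length(taps) < 3) {
    stop("CoV requires at least 3 taps (2 inter-response intervals)",
         call. = FALSE)
  }
  iri <- diff(taps)
  stats::sd(iri) / mean(iri)
}

#' Validate a tapping trial before scoring
#'
#' A trial is invalid if it has fewer than `min_taps` taps (boundary
#' inclusive: exactly `min_taps` is valid) or if no tap falls at or after
#' the initial listening window (participants tap once they have found the
#' beat, so trials whose taps all precede the window carry no usable
#' synchronisation). Invalid trials propagate as missing scores, never as
#' zeros.
#'
#' @inheritParams asynchrony_score
#' @param min_taps Minimum tap count for a scorable trial (default 4, which
#'   also guarantees CoV is computable).
#' @param listen_window Seconds from excerpt start treated as beat-finding
#'   time; default 0 (no window).
#' @return A list with `valid` (logical) and `reason` (`NA` or one of
#'   `"too_few_taps"`, `"no_taps_after_window"`).
#' @export
validate_trial <- function(taps, grid, min_taps = 4, listen_window = 0) {
  taps <- as.numeric(taps)
  if (length(taps) < min_taps) {
    return(list(valid = FALSE, reason = "too_few_taps"))
  }
  if (listen_window > 0 && all(taps < listen_window)) {
    return(list(valid = FALSE, reason = "no_taps_after_window"))
  }
  list(valid = TRUE, reason = NA_character_)
}

#' Score every trial of a tap log
#'
#' Applies the validity filter and the three production scores to each
#' (participant, excerpt, repetition) trial. Invalid trials keep their row
#' with `NA` scores and a machine-readable reason.
#'
#' @param tap_log Tibble with columns `participant_id`, `excerpt_id`,
#'   `repetition`, `tap_onset_s` (one row per tap), as produced by
#'   [simulate_cohort()] or [read_tap_log()].
#' @param grids Named list of `bat_grid` objects keyed by excerpt id.
#' @param min_taps,listen_window Passed to [validate_trial()].
#' @param cdev_variant Passed to [cdev_score()].
#' @return A tibble with one row per trial: ids, `n_taps`, `valid`,
#'   `reason`, `asynchrony`, `cdev`, `cov`.
#' @export
score_trials <- function(tap_log, grids, min_taps = 4, listen_window = 0,
                         cdev_variant = c("per-interval", "aggregate")) {
  cdev_variant <- match.arg(cdev_variant)
  need <- c("participant_id", "excerpt_id", "repetition", "tap_onset_s")
  missing_cols <- setdiff(need, names(tap_log))
  if (length(missing_cols)) {
    stop("tap log is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(tap_log$excerpt_id), names(grids))
  if (length(unknown)) {
    stop("no beat grid for excerpt(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # fully vectorised over the whole log: trials are contiguous after the
  # sort, so per-trial means reduce to rowsum() over a trial index
  ord <- order(tap_log$participant_id, tap_log$excerpt_id,
               tap_log$repetition, tap_log$tap_onset_s)
  tl <- as.data.frame(tap_log)[ord, , drop = FALSE]
  key <- paste(tl$participant_id, tl$excerpt_id, tl$repetition, sep = "\r")
  tid <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  n_trials <- tid[length(tid)]
  n_taps <- tabulate(tid, nbins = n_trials)
  first_ix <- which(c(TRUE, key[-1] != key[-length(key)]))
  last_ix <- cumsum(n_taps)

  mibi_by_ex <- vapply(grids, mean_ibi, numeric(1))
  ex_row <- match(tl$excerpt_id, names(grids))
  mibi_row <- mibi_by_ex[ex_row]

  # nearest-beat distance per tap, excerpt by excerpt
  dist <- numeric(nrow(tl))
  for (ex in unique(tl$excerpt_id)) {
    rows <- which(tl$excerpt_id == ex)
    beats <- grids[[ex]]$beat_onsets
    idx <- nearest_beat_index(tl$tap_onset_s[rows], beats)
    dist[rows] <- abs(tl$tap_onset_s[rows] - beats[idx])
  }
  by_trial <- function(x, index, nbins) {
    out <- rep(NA_real_, nbins)
    if (length(x)) {
      s <- rowsum(x, index)
      out[as.integer(rownames(s))] <- s[, 1]
    }
    out
  }
  async <- by_trial(dist / mibi_row, tid, n_trials) / n_taps

  # inter-response intervals: consecutive diffs within a trial
  d_all <- diff(tl$tap_onset_s)
  same <- tid[-1] == tid[-length(tid)]
  iri <- d_all[same]
  iri_tid <- tid[-1][same]
  iri_mibi <- mibi_row[-1][same]
  n_iri <- tabulate(iri_tid, nbins = n_trials)
  sum_iri <- by_trial(iri, iri_tid, n_trials)
  mean_iri <- sum_iri / n_iri
  cdev <- if (cdev_variant == "per-interval") {
    by_trial(abs(iri - iri_mibi) / iri_mibi, iri_tid, n_trials) / n_iri
  } else {
    abs(mean_iri - mibi_row[first_ix]) / mibi_row[first_ix]
  }
  # centred sum of squares (two-pass): stable when IRIs are constant
  centred <- iri - mean_iri[iri_tid]
  var_iri <- by_trial(centred^2, iri_tid, n_trials) / (n_iri - 1)
  cov <- sqrt(pmax(var_iri, 0)) / mean_iri
  cov[n_iri < 2] <- NA_real_
  cdev[n_iri < 1] <- NA_real_

  valid <- n_taps >= min_taps
  reason <- rep(NA_character_, n_trials)
  reason[!valid] <- "too_few_taps"
  if (listen_window > 0) {
    all_before <- tl$tap_onset_s[last_ix] < listen_window
    reason[valid & all_before] <- "no_taps_after_window"
    valid <- valid & !all_before
  }
  async[!valid] <- NA_real_
  cdev[!valid] <- NA_real_
  cov[!valid] <- NA_real_
  tibble::tibble(
    participant_id = tl$participant_id[first_ix],
    excerpt_id = tl$excerpt_id[first_ix],
    repetition = tl$repetition[first_ix],
    n_taps = n_taps, valid = valid, reason = reason,
    asynchrony = async, cdev = cdev, cov = cov)
}

#' Aggregate trial scores and responses into participant-level scores
#'
#' Production scores are averaged in two stages: the two consecutive
#' repetitions of each excerpt are averaged first (a lone valid repetition
#' stands alone), then excerpt means are averaged, so every excerpt carries
#' equal weight regardless of missing repetitions. Perception accuracy is
#' the percent of correct test-trial judgments. Participants with no valid
#' production trial or no responses get `NA` scores and are flagged
#' `excluded`.
#'
#' @param trial_scores Output of [score_trials()].
#' @param responses Tibble with columns `participant_id`, `judgment`,
#'   `truth` (test trials only; practice is excluded upstream).
#' @return A tibble with one row per participant: `pct_correct`,
#'   `asynchrony`, `cdev`, `cov`, `n_valid_trials`, `n_responses`,
#'   `excluded`.
#' @export
aggregate_participants <- function(trial_scores, responses) {
  prod <- trial_scores |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$participant_id, .data$excerpt_id) |>
    dplyr::summarise(
      asynchrony = mean(.data$asynchrony, na.rm = TRUE),
      cdev = mean(.data$cdev, na.rm = TRUE),
      cov = mean(.data$cov, na.rm = TRUE),
      n_valid = dplyr::n(), .groups = "drop_last") |>
    dplyr::summarise(
      asynchrony = mean(.data$asynchrony, na.rm = TRUE),
      cdev = mean(.data$cdev, na.rm = TRUE),
      cov = mean(.data$cov, na.rm = TRUE),
      n_valid_trials = sum(.data$n_valid), .groups = "drop")
  if (is.null(responses) || nrow(responses) == 0) {
    responses <- tibble::tibble(participant_id = character())
    perc <- tibble::tibble(participant_id = character(),
                           pct_correct = numeric(),
                           n_responses = integer())
  } else {
    perc <- responses |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(
        pct_correct = percent_correct(.data$judgment, .data$truth),
        n_responses = dplyr::n(), .groups = "drop")
  }
  all_ids <- union(unique(trial_scores$participant_id),
                   unique(responses$participant_id))
  out <- tibble::tibble(participant_id = sort(all_ids)) |>
    dplyr::left_join(perc, by = "participant_id") |>
    dplyr::left_join(prod, by = "participant_id") |>
    dplyr::mutate(
      n_valid_trials = dplyr::coalesce(.data$n_valid_trials, 0L),
      n_responses = dplyr::coalesce(.data$n_responses, 0L),
      excluded = .data$n_valid_trials == 0 | .data$n_responses == 0)
  dplyr::relocate(out, "participant_id", "pct_correct", "asynchrony",
                  "cdev", "cov", "n_valid_trials", "n_responses", "excluded")
}

#' Score a whole cohort
#'
#' Convenience wrapper: scores all tapping trials, aggregates to
#' participant level and joins demographics (with training bins from
#' [categorize_training()] if not already present).
#'
#' @param cohort A `bat_cohort` from [simulate_cohort()], or a list with
#'   elements `taps`, `responses`, `demographics`, `grids`.
#' @param min_taps,listen_window,cdev_variant Passed to [score_trials()].
#' @param training_cutoff Years cutoff for the training bins (default 3:
#'   0-2 vs 3+ years).
#' @return A participant-level tibble (one row each) with demographics,
#'   training bins and the four scores -- the input expected by
#'   [factorial_anova()] and [bayes_anova()].
#' @export
score_cohort <- function(cohort, min_taps = 4, listen_window = 0,
                         cdev_variant = c("per-interval", "aggregate"),
                         training_cutoff = 3) {
  cdev_variant <- match.arg(cdev_variant)
  trial_scores <- score_trials(cohort$taps, cohort$grids,
                               min_taps = min_taps,
                               listen_window = listen_window,
                               cdev_variant = cdev_variant)
  scores <- aggregate_participants(trial_scores, cohort$responses)
  demo <- cohort$demographics
  if (!"music_bin" %in% names(demo)) {
    demo$music_bin <- categorize_training(demo$music_years, training_cutoff)
  }
  if (!"dance_bin" %in% names(demo) && "dance_years" %in% names(demo)) {
    demo$dance_bin <- categorize_training(demo$dance_years, training_cutoff)
  }
  dplyr::inner_join(demo, scores, by = "participant_id")
}
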