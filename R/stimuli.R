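# Stimulus construction: beat grids, alignment conditions, perturbed click
# tracks and trial batteries for the Beat Alignment Test perception task.

#' Beat grid of a musical excerpt
#'
#' A beat grid holds the annotated (or constructed) beat onset times of one
#' musical excerpt, in seconds from excerpt start. The grid is the reference
#' against which both click-track misalignment and tapping accuracy are
#' measured; its mean inter-beat interval (IBI) is the normalising unit for
#' all production scores.
#'
#' @param beat_onsets Numeric vector of beat onset times in seconds,
#'   strictly increasing, length at least 2.
#' @param excerpt_id Identifier for the excerpt.
#' @param duration Excerpt duration in seconds. Defaults to the last beat
#'   onset plus one mean IBI, so the grid always spans its own beats.
#' @return An object of class `bat_grid` with fields `excerpt_id`,
#'   `beat_onsets` and `duration`.
#' @seealso [make_beat_grid()] for isochronous grids, [mean_ibi()]
#' @export
#' @examples
#' g <- beat_grid(c(0, 0.5, 1, 1.5), excerpt_id = "ex1")
#' mean_ibi(g)
beat_grid <- function(beat_onsets, excerpt_id = "excerpt", duration = NULL) {
  if (!is.numeric(beat_onsets) || length(beat_onsets) < 2 ||
      any(!is.finite(beat_onsets))) {
    stop("`beat_onsets` must be a finite numeric vector of length >= 2",
         call. = FALSE)
  }
  beat_onsets <- as.numeric(beat_onsets)
  if (any(diff(beat_onsets) <= 0)) {
    stop("beat onsets must be strictly increasing", call. = FALSE)
  }
  if (beat_onsets[1] < 0) {
    stop("beat onsets must be non-negative", call. = FALSE)
  }
  if (is.null(duration)) {
    duration <- beat_onsets[length(beat_onsets)] + mean(diff(beat_onsets))
  }
  if (!is.numeric(duration) || length(duration) != 1 ||
      duration < beat_onsets[length(beat_onsets)]) {
    stop("`duration` must be a single number >= the last beat onset",
         call. = FALSE)
  }
  structure(
    list(excerpt_id = as.character(excerpt_id),
         beat_onsets = beat_onsets,
         duration = as.numeric(duration)),
    class = "bat_grid"
  )
}

#' Construct an isochronous beat grid
#'
#' Builds a metronomic grid at a fixed tempo. Isochronous grids are the
#' default fixture throughout the package; annotated (irregular) grids from
#' real excerpts are accepted anywhere a grid is, with the mean IBI used in
#' all normalisations.
#'
#' @param tempo_bpm Tempo in beats per minute, positive.
#' @param n_beats Number of beats, at least 2.
#' @param first_onset Time of the first beat in seconds.
#' @inheritParams beat_grid
#' @return A `bat_grid` whose onsets are `first_onset + k * 60 / tempo_bpm`
#'   for `k = 0, ..., n_beats - 1`.
#' @export
#' @examples
#' make_beat_grid(120, 5) # beats at 0, 0.5, 1, 1.5, 2 s
make_beat_grid <- function(tempo_bpm, n_beats, first_onset = 0,
                           excerpt_id = "excerpt") {
  if (!is.numeric(tempo_bpm) || length(tempo_bpm) != 1 || tempo_bpm <= 0) {
    stop("`tempo_bpm` must be a single positive number", call. = FALSE)
  }
  n_beats <- as.integer(n_beats)
  if (is.na(n_beats) || n_beats < 2) {
    stop("`n_beats` must be an integer >= 2", call. = FALSE)
  }
  ibi <- 60 / tempo_bpm
  onsets <- first_onset + (seq_len(n_beats) - 1) * ibi
  beat_grid(onsets, excerpt_id = excerpt_id)
}

#' Mean inter-beat interval of a grid
#'
#' @param grid A `bat_grid`.
#' @return Mean of consecutive beat onset differences, in seconds.
#' @export
mean_ibi <- function(grid) {
  stopifnot(inherits(grid, "bat_grid"))
  mean(diff(grid$beat_onsets))
}

#' @export
print.bat_grid <- function(x, ...) {
  cat(sprintf("<bat_grid> %s: %d beats, mean IBI %.4f s, duration %.2f s\n",
              x$excerpt_id, length(x$beat_onsets), mean_ibi(x), x$duration))
  invisible(x)
}

#' Alignment condition for a perception trial
#'
#' Describes how a click track relates to the musical beat: `"on_beat"`
#' (beeps on the beat), `"phase"` (beeps displaced by a fixed fraction of
#' the mean IBI, constant misalignment) or `"period"` (beeps at a tempo
#' differing by a fixed percentage, accumulating misalignment). The BAT
#' design uses phase shifts of 10% or 17.5% of the IBI and period shifts
#' of 2% of the tempo.
#'
#' @param kind One of `"on_beat"`, `"phase"`, `"period"`.
#' @param magnitude Dimensionless shift fraction, in (0, 0.5) for phase and
#'   period conditions; 0 (or omitted) for on-beat.
#' @param direction `-1` for early/fast, `+1` for late/slow; 0 for on-beat.
#' @return An object of class `bat_condition`.
#' @export
#' @examples
#' alignment_condition("phase", 0.175, -1)  # beeps 17.5% of an IBI early
#' alignment_condition("on_beat")
alignment_condition <- function(kind = c("on_beat", "phase", "period"),
                                magnitude = 0, direction = 0) {
  kind <- match.arg(kind)
  if (kind == "on_beat") {
    if (!isTRUE(all.equal(as.numeric(magnitude), 0))) {
      stop("on-beat conditions must have zero magnitude", call. = FALSE)
    }
    magnitude <- 0
    direction <- 0L
  } else {
    if (!is.numeric(magnitude) || length(magnitude) != 1 ||
        magnitude <= 0 || magnitude >= 0.5) {
      stop(sprintf("`magnitude` must lie in (0, 0.5) for %s conditions", kind),
           call. = FALSE)
    }
    if (!direction %in% c(-1, 1)) {
      stop("`direction` must be -1 (early/fast) or +1 (late/slow)",
           call. = FALSE)
    }
  }
  structure(
    list(kind = kind, magnitude = as.numeric(magnitude),
         direction = as.integer(direction)),
    class = "bat_condition"
  )
}

#' @export
print.bat_condition <- function(x, ...) {
  if (x$kind == "on_beat") {
    cat("<bat_condition> on_beat\n")
  } else {
    dir <- if (x$direction < 0) "early/fast" else "late/slow"
    cat(sprintf("<bat_condition> %s %.3f %s\n", x$kind, x$magnitude, dir))
  }
  invisible(x)
}

new_click_track <- function(grid, condition, beep_onsets, beep_start) {
  if (beep_start < 0) stop("`beep_start` must be >= 0", call. = FALSE)
  if (length(beep_onsets) < 1) {
    stop("no beeps fall within the excerpt; lower `beep_start`",
         call. = FALSE)
  }
  if (any(diff(beep_onsets) <= 0)) {
    stop("internal error: beep onsets not strictly increasing", call. = FALSE)
  }
  structure(
    list(excerpt_id = grid$excerpt_id, condition = condition,
         beep_onsets = as.numeric(beep_onsets),
         beep_start = as.numeric(beep_start)),
    class = "bat_click_track"
  )
}

#' @export
print.bat_click_track <- function(x, ...) {
  cat(sprintf("<bat_click_track> %s (%s): %d beeps from %.2f s\n",
              x$excerpt_id, x$condition$kind, length(x$beep_onsets),
              x$beep_start))
  invisible(x)
}

#' On-beat click track
#'
#' Beeps placed exactly on the beats at or after `beep_start` (in the BAT,
#' beeps begin 5 seconds into the music).
#'
#' @param grid A `bat_grid`.
#' @param beep_start Offset into the excerpt, in seconds, at which beeps
#'   begin.
#' @return A `bat_click_track`.
#' @export
on_beat_track <- function(grid, beep_start = 0) {
  stopifnot(inherits(grid, "bat_grid"))
  beats <- grid$beat_onsets[grid$beat_onsets >= beep_start]
  new_click_track(grid, alignment_condition("on_beat"), beats, beep_start)
}

#' Phase-shifted click track
#'
#' Displaces every beep from its beat by a constant `direction * magnitude *
#' mean IBI`: a pure phase error whose size does not grow over the excerpt.
#' Beeps are generated for the beats at or after `beep_start`.
#'
#' @inheritParams on_beat_track
#' @param magnitude Fraction of the mean IBI to shift by, in (0, 0.5);
#'   the BAT uses 0.10 and 0.175.
#' @param direction `-1` shifts beeps early, `+1` late.
#' @return A `bat_click_track` with `condition$kind == "phase"`.
#' @export
#' @examples
#' g <- make_beat_grid(120, 10)
#' apply_phase_shift(g, 0.10, -1)$beep_onsets  # each beep 0.05 s early
apply_phase_shift <- function(grid, magnitude, direction, beep_start = 0) {
  stopifnot(inherits(grid, "bat_grid"))
  cond <- alignment_condition("phase", magnitude, direction)
  beats <- grid$beat_onsets[grid$beat_onsets >= beep_start]
  beeps <- beats + cond$direction * cond$magnitude * mean_ibi(grid)
  new_click_track(grid, cond, beeps, beep_start)
}

#' Period-shifted click track
#'
#' Beeps at a tempo `1 + direction * magnitude` times the excerpt's mean
#' beat period: a pure period (tempo) error. The first beep is anchored on
#' the first beat at or after `beep_start`, so the track starts phase
#' aligned and drifts linearly thereafter -- beep `k` is misaligned by
#' `k * magnitude` IBIs. Beeps are generated until the excerpt's duration
#' is reached.
#'
#' @inheritParams apply_phase_shift
#' @param magnitude Fractional tempo change, in (0, 0.5); the BAT uses 0.02.
#' @param direction `+1` for slower beeps (longer period), `-1` for faster.
#' @return A `bat_click_track` with `condition$kind == "period"`.
#' @export
#' @examples
#' g <- make_beat_grid(120, 10)
#' apply_period_shift(g, 0.02, +1)$beep_onsets  # spacing 0.51 s
apply_period_shift <- function(grid, magnitude, direction, beep_start = 0) {
  stopifnot(inherits(grid, "bat_grid"))
  cond <- alignment_condition("period", magnitude, direction)
  beats <- grid$beat_onsets[grid$beat_onsets >= beep_start]
  if (length(beats) == 0) {
    stop("no beats at or after `beep_start`", call. = FALSE)
  }
  anchor <- beats[1]
  step <- mean_ibi(grid) * (1 + cond$direction * cond$magnitude)
  n <- max(1L, floor((grid$duration - anchor) / step) + 1L)
  beeps <- anchor + (seq_len(n) - 1) * step
  new_click_track(grid, cond, beeps, beep_start)
}

#' Build a click track for an arbitrary condition
#'
#' @inheritParams on_beat_track
#' @param condition A `bat_condition`.
#' @return A `bat_click_track`.
#' @export
make_click_track <- function(grid, condition, beep_start = 0) {
  stopifnot(inherits(condition, "bat_condition"))
  switch(condition$kind,
    on_beat = on_beat_track(grid, beep_start),
    phase = apply_phase_shift(grid, condition$magnitude, condition$direction,
                              beep_start),
    period = apply_period_shift(grid, condition$magnitude,
                                condition$direction, beep_start)
  )
}

#' Default 17-trial condition plan
#'
#' A balanced example plan for the 17 test trials of a perception battery:
#' 5 on-beat trials, 6 phase-shifted trials covering both magnitudes (10%
#' and 17.5% of the IBI) in both directions, and 6 period-shifted trials (2%
#' fast and 2% slow, three each). Batteries are fully configurable; this
#' plan is one reasonable instantiation, not a canonical stimulus list.
#'
#' @return A list of 17 `bat_condition` objects.
#' @export
default_condition_plan <- function() {
  c(
    replicate(5, alignment_condition("on_beat"), simplify = FALSE),
    list(
      alignment_condition("phase", 0.10, -1),
      alignment_condition("phase", 0.10, +1),
      alignment_condition("phase", 0.175, -1),
      alignment_condition("phase", 0.175, +1),
      alignment_condition("phase", 0.10, -1),
      alignment_condition("phase", 0.175, -1)
    ),
    c(replicate(3, alignment_condition("period", 0.02, -1), simplify = FALSE),
      replicate(3, alignment_condition("period", 0.02, +1), simplify = FALSE))
  )
}

#' Assemble a perception-task trial battery
#'
#' Pairs excerpts with alignment conditions and returns practice trials
#' followed by test trials in a seeded random order. Each trial's `truth`
#' flag is `TRUE` exactly when its condition is on-beat. Beeps begin
#' `beep_start` seconds into each excerpt (5 s by default, matching the BAT
#' design).
#'
#' @param excerpts List of `bat_grid` objects; must contain at least
#'   `n_practice + length(condition_plan)` grids.
#' @param condition_plan List of `bat_condition` objects, one per test
#'   trial (17 in the standard battery).
#' @param n_practice Number of practice trials prepended to the battery.
#' @param practice_plan Optional list of conditions for the practice trials;
#'   defaults to all on-beat.
#' @param beep_start Seconds into each excerpt at which beeps begin.
#' @param seed Integer seed controlling the test-trial order; the same seed
#'   always yields the same battery.
#' @return A tibble with one row per trial: `trial_index`, `phase`
#'   (`"practice"` or `"test"`), `excerpt_id`, `kind`, `magnitude`,
#'   `direction`, `truth`, `beep_start`.
#' @export
#' @examples
#' grids <- lapply(1:20, function(i)
#'   make_beat_grid(100 + i, 20, excerpt_id = paste0("ex", i)))
#' bat <- build_battery(grids, default_condition_plan(), seed = 1)
#' table(bat$phase, bat$kind)
build_battery <- function(excerpts, condition_plan = default_condition_plan(),
                          n_practice = 3, practice_plan = NULL,
                          beep_start = 5, seed = 1) {
  stopifnot(is.list(excerpts),
            all(vapply(excerpts, inherits, logical(1), "bat_grid")))
  n_test <- length(condition_plan)
  if (n_test < 1) stop("`condition_plan` must be non-empty", call. = FALSE)
  if (is.null(practice_plan)) {
    practice_plan <- replicate(n_practice, alignment_condition("on_beat"),
                               simplify = FALSE)
  }
  if (length(practice_plan) != n_practice) {
    stop("`practice_plan` must have `n_practice` conditions", call. = FALSE)
  }
  if (length(excerpts) < n_practice + n_test) {
    stop(sprintf("need at least %d excerpts (%d practice + %d test), got %d",
                 n_practice + n_test, n_practice, n_test, length(excerpts)),
         call. = FALSE)
  }
  ids <- vapply(excerpts, function(g) g$excerpt_id, character(1))
  if (anyDuplicated(ids)) {
    stop("excerpt ids must be unique", call. = FALSE)
  }
  test_ids <- ids[n_practice + seq_len(n_test)]
  order_idx <- withr::with_seed(seed, sample.int(n_test))

  cond_row <- function(cond) {
    data.frame(kind = cond$kind, magnitude = cond$magnitude,
               direction = cond$direction)
  }
  practice <- if (n_practice > 0) {
    cbind(data.frame(excerpt_id = ids[seq_len(n_practice)],
                     phase = "practice"),
          do.call(rbind, lapply(practice_plan, cond_row)))
  }
  test <- cbind(data.frame(excerpt_id = test_ids[order_idx], phase = "test"),
                do.call(rbind, lapply(condition_plan[order_idx], cond_row)))
  out <- rbind(practice, test)
  out$trial_index <- seq_len(nrow(out))
  out$truth <- out$kind == "on_beat"
  out$beep_start <- beep_start
  tibble::as_tibble(out[, c("trial_index", "phase", "excerpt_id", "kind",
                            "magnitude", "direction", "truth", "beep_start")])
}

#' A deterministic set of stand-in excerpt grids
#'
#' Twenty isochronous grids spanning tempos from 80 to 140 bpm and durations
#' from 10 to 16 seconds, mirroring the published battery's excerpt duration
#' range. These are synthetic stand-ins for annotated musical excerpts: real
#' beat annotations can be loaded with [read_beat_annotations()] and used
#' anywhere these are.
#'
#' @param n Number of excerpts (default 20: 3 practice + 17 test).
#' @return A named list of `bat_grid` objects.
#' @export
default_excerpts <- function(n = 20) {
  stopifnot(n >= 1)
  tempos <- round(seq(80, 140, length.out = n))
  durations <- rep(c(10, 12, 14, 16, 11, 13, 15), length.out = n)
  grids <- lapply(seq_len(n), function(i) {
    ibi <- 60 / tempos[i]
    n_beats <- floor(durations[i] / ibi)
    make_beat_grid(tempos[i], n_beats, first_onset = ibi / 2,
                   excerpt_id = sprintf("ex%02d", i))
  })
  names(grids) <- vapply(grids, function(g) g$excerpt_id, character(1))
  grids
}
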