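# Readers and writers for the delimited-text interchange formats: beat
# annotations, tap logs, perception responses, demographics and result
# tables. All files are comma-separated UTF-8 with a header row; times are
# in seconds.

check_schema <- function(df, need, what) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop(sprintf("%s contains no rows", what), call. = FALSE)
  }
  invisible(df)
}

read_csv_strict <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    stop(sprintf("%s is empty: %s", what, path), call. = FALSE)
  }
  df
}

#' Read beat annotations
#'
#' @param path CSV with columns `excerpt_id`, `beat_onset_s` (one row per
#'   beat; an optional `duration_s` column sets the excerpt duration).
#' @return A tibble of annotations; convert to grids with
#'   [grids_from_annotations()].
#' @export
read_beat_annotations <- function(path) {
  df <- read_csv_strict(path, "beat annotation file")
  check_schema(df, c("excerpt_id", "beat_onset_s"), "beat annotation file")
  df
}

#' Convert a beat annotation table into beat grids
#'
#' @param annotations Tibble from [read_beat_annotations()].
#' @return Named list of `bat_grid` objects keyed by excerpt id.
#' @export
grids_from_annotations <- function(annotations) {
  check_schema(annotations, c("excerpt_id", "beat_onset_s"),
               "beat annotation table")
  split_df <- split(annotations, annotations$excerpt_id)
  grids <- lapply(split_df, function(d) {
    dur <- if ("duration_s" %in% names(d)) d$duration_s[1] else NULL
    beat_grid(sort(d$beat_onset_s), excerpt_id = d$excerpt_id[1],
              duration = dur)
  })
  grids
}

#' Write beat grids as an annotation table
#'
#' @param grids Named list of `bat_grid` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_beat_annotations <- function(grids, path) {
  rows <- lapply(grids, function(g) {
    tibble::tibble(excerpt_id = g$excerpt_id, beat_onset_s = g$beat_onsets,
                   duration_s = g$duration)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Read a tap log
#'
#' @param path CSV with columns `participant_id`, `excerpt_id`,
#'   `repetition`, `tap_onset_s` (one row per tap). Repetitions must be 1
#'   or 2; duplicate onsets within a trial are dropped with a warning.
#' @return A tibble sorted by participant, excerpt, repetition, onset.
#' @export
read_tap_log <- function(path) {
  df <- read_csv_strict(path, "tap log")
  check_schema(df, c("participant_id", "excerpt_id", "repetition",
                     "tap_onset_s"), "tap log")
  if (!all(df$repetition %in% c(1, 2))) {
    bad <- unique(df$repetition[!df$repetition %in% c(1, 2)])
    stop("tap log `repetition` must be 1 or 2; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$participant_id, .data$excerpt_id,
                       .data$repetition, .data$tap_onset_s)
  dup <- duplicated(df[, c("participant_id", "excerpt_id", "repetition",
                           "tap_onset_s")])
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate tap onset(s)", sum(dup)),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Write a tap log
#'
#' @param taps Tibble with the tap log columns (see [read_tap_log()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tap_log <- function(taps, path) {
  check_schema(taps, c("participant_id", "excerpt_id", "repetition",
                       "tap_onset_s"), "tap log")
  readr::write_csv(taps, path)
  invisible(path)
}

#' Read perception responses
#'
#' @param path CSV with columns `participant_id`, `trial_index`,
#'   `judgment`, `truth` (both `"on"`/`"off"`), `confidence` (integer 1-7,
#'   stored but not analysed).
#' @return A tibble of responses.
#' @export
read_responses <- function(path) {
  df <- read_csv_strict(path, "response log")
  check_schema(df, c("participant_id", "trial_index", "judgment", "truth",
                     "confidence"), "response log")
  for (col in c("judgment", "truth")) {
    bad <- !df[[col]] %in% c("on", "off")
    if (any(bad)) {
      stop(sprintf("response log `%s` must be \"on\" or \"off\" (row %d)",
                   col, which(bad)[1]), call. = FALSE)
    }
  }
  bad_conf <- !(df$confidence %in% 1:7)
  if (any(bad_conf)) {
    stop(sprintf("response log `confidence` must be an integer 1-7 (row %d)",
                 which(bad_conf)[1]), call. = FALSE)
  }
  df
}

#' Write perception responses
#'
#' @param responses Tibble with the response columns (see
#'   [read_responses()]); `truth` may be logical, written as on/off.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_responses <- function(responses, path) {
  if (is.logical(responses$truth)) {
    responses$truth <- ifelse(responses$truth, "on", "off")
  }
  check_schema(responses, c("participant_id", "trial_index", "judgment",
                            "truth", "confidence"), "response log")
  readr::write_csv(responses, path)
  invisible(path)
}

#' Read a demographics table
#'
#' @param path CSV with columns `participant_id`, `group`, `age`,
#'   `music_years`, `dance_years`.
#' @param training_cutoff Cutoff passed to [categorize_training()] to add
#'   `music_bin` and `dance_bin` columns.
#' @return A tibble with binned training columns.
#' @export
read_demographics <- function(path, training_cutoff = 3) {
  df <- read_csv_strict(path, "demographics table")
  check_schema(df, c("participant_id", "group", "age", "music_years",
                     "dance_years"), "demographics table")
  df$music_bin <- categorize_training(df$music_years, training_cutoff)
  df$dance_bin <- categorize_training(df$dance_years, training_cutoff)
  df
}

#' Write result tables to a directory
#'
#' Each table in the named list is written as `<name>.csv` in long/tidy
#' format (one row per participant-score, per effect, or per model).
#' Numeric columns keep full precision.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory, created if needed.
#' @return Character vector of paths written, invisibly.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(tables[[nm]]), p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a simulated cohort to a directory
#'
#' Writes `demographics.csv`, `responses.csv`, `taps.csv`, `beats.csv` and
#' `battery.csv` so a simulated cohort can round-trip through the file
#' readers exactly as real data would.
#'
#' @param cohort A `bat_cohort`.
#' @param dir Output directory, created if needed.
#' @return Character vector of paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tap_log(cohort$taps, file.path(dir, "taps.csv"))
  write_responses(cohort$responses, file.path(dir, "responses.csv"))
  readr::write_csv(cohort$demographics, file.path(dir, "demographics.csv"))
  write_beat_annotations(cohort$grids, file.path(dir, "beats.csv"))
  readr::write_csv(cohort$battery, file.path(dir, "battery.csv"))
  invisible(file.path(dir, c("taps.csv", "responses.csv",
                             "demographics.csv", "beats.csv",
                             "battery.csv")))
}
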