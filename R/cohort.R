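# Synthetic cohort simulation: parametric perceiver and tapper models and
# full virtual cohorts with known group/training effects. These stand in
# for human data so the scoring and statistics pipeline can be validated
# against ground truth.

#' Perceiver parameters for the perception-task response model
#'
#' The perceiver responds "off" with lapse-adjusted logistic probability
#' `lapse + (1 - 2 * lapse) * plogis(sensitivity * misalignment - bias)`,
#' where misalignment is the trial's normalised shift (see
#' [prob_respond_off()]). `sensitivity` is the psychometric slope (0 =
#' guessing), `bias` shifts the criterion toward responding "on" (positive
#' bias makes on-beat trials more likely to be judged on-beat), and
#' `lapse_rate` is the probability mass of stimulus-independent errors.
#'
#' @param sensitivity Non-negative psychometric slope (logit units per unit
#'   of normalised misalignment).
#' @param lapse_rate Lapse probability in `[0, 0.5]`.
#' @param bias Criterion shift toward "on", in logit units (typical range
#'   `[-1, 1]` times a few).
#' @return An object of class `bat_perceiver`.
#' @export
perceiver_params <- function(sensitivity, lapse_rate = 0, bias = 0) {
  if (!is.numeric(sensitivity) || sensitivity < 0) {
    stop("`sensitivity` must be >= 0", call. = FALSE)
  }
  if (lapse_rate < 0 || lapse_rate > 0.5) {
    stop("`lapse_rate` must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(sensitivity = as.numeric(sensitivity),
                 lapse_rate = as.numeric(lapse_rate),
                 bias = as.numeric(bias)),
            class = "bat_perceiver")
}

#' Tapper parameters for the production-task generative model
#'
#' The tapper is a linear-phase model: intended tap `k` lands at
#' `beat_1 + start_latency + (beat_k - beat_1) * period_scale +
#' phase_offset_frac * mean IBI + N(0, (motor_noise_frac * mean IBI)^2)`.
#' Its parameters map one-to-one onto the production scores: with no noise
#' or misses, asynchrony recovers `|phase_offset_frac|` and CDEV recovers
#' `|period_scale - 1|` exactly on isochronous grids.
#'
#' @param phase_offset_frac Signed constant tap offset as a fraction of the
#'   mean IBI (negative = anticipation, the usual human tendency).
#' @param period_scale Multiplicative tempo error; 1 = perfect tempo.
#' @param motor_noise_frac SD of Gaussian tap jitter as a fraction of the
#'   mean IBI.
#' @param miss_prob Probability each intended tap is omitted.
#' @param extra_prob Expected number of spurious taps per intended tap.
#' @param start_latency Seconds added before the first tap.
#' @return An object of class `bat_tapper`.
#' @export
tapper_params <- function(phase_offset_frac = 0, period_scale = 1,
                          motor_noise_frac = 0, miss_prob = 0,
                          extra_prob = 0, start_latency = 0) {
  if (period_scale <= 0) stop("`period_scale` must be > 0", call. = FALSE)
  if (motor_noise_frac < 0) {
    stop("`motor_noise_frac` must be >= 0", call. = FALSE)
  }
  if (miss_prob < 0 || miss_prob >= 1 || extra_prob < 0 || extra_prob >= 1) {
    stop("`miss_prob` and `extra_prob` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(phase_offset_frac = as.numeric(phase_offset_frac),
                 period_scale = as.numeric(period_scale),
                 motor_noise_frac = as.numeric(motor_noise_frac),
                 miss_prob = as.numeric(miss_prob),
                 extra_prob = as.numeric(extra_prob),
                 start_latency = as.numeric(start_latency)),
            class = "bat_tapper")
}

#' Normalised misalignment of a trial condition
#'
#' On-beat trials have misalignment 0. Phase trials have misalignment equal
#' to the shift magnitude (a constant offset in IBI units). For period
#' trials the 2% tempo error is perceptually a drift, not a fixed offset,
#' so the magnitude is scaled by `period_drift_factor`: beep `k` of a
#' period-shifted track is misaligned by `k * magnitude` IBIs, so the mean
#' misalignment over a train of `K` beeps is `magnitude * (K - 1) / 2`.
#' The default factor of 8 corresponds to the roughly 12-20 beep trains the
#' standard battery produces.
#'
#' @param kind Condition kind (`"on_beat"`, `"phase"`, `"period"`).
#' @param magnitude Shift magnitude fraction.
#' @param period_drift_factor Multiplier converting a period magnitude into
#'   an effective mean misalignment.
#' @return Non-negative misalignment in IBI units.
#' @export
misalignment <- function(kind, magnitude, period_drift_factor = 8) {
  ifelse(kind == "on_beat", 0,
         ifelse(kind == "phase", magnitude,
                magnitude * period_drift_factor))
}

#' Closed-form probability of responding "off the beat"
#'
#' @param p A `bat_perceiver`.
#' @inheritParams misalignment
#' @return Probability in `[0, 1]` (vectorised over trials).
#' @export
#' @examples
#' p <- perceiver_params(sensitivity = 5)
#' prob_respond_off(p, "phase", 0.175)  # plogis(0.875)
prob_respond_off <- function(p, kind, magnitude, period_drift_factor = 8) {
  stopifnot(inherits(p, "bat_perceiver"))
  m <- misalignment(kind, magnitude, period_drift_factor)
  p$lapse_rate + (1 - 2 * p$lapse_rate) *
    stats::plogis(p$sensitivity * m - p$bias)
}

#' Simulate perception judgments for a battery
#'
#' Draws an on/off judgment and a 1-7 confidence rating for each trial.
#' Confidence grows monotonically with the distance of the response
#' probability from the 0.5 decision threshold, with one step of uniform
#' rating jitter; it is carried as metadata only and not analysed further.
#'
#' @param p A `bat_perceiver`.
#' @param battery Trial tibble from [build_battery()] (practice trials are
#'   kept if present; filter on `phase` upstream as needed).
#' @param period_drift_factor Passed to [prob_respond_off()].
#' @return The battery tibble with added `judgment` (`"on"`/`"off"`),
#'   `truth_label` and `confidence` columns.
#' @export
simulate_judgments <- function(p, battery, period_drift_factor = 8) {
  pr_off <- prob_respond_off(p, battery$kind, battery$magnitude,
                             period_drift_factor)
  n <- length(pr_off)
  judgment <- ifelse(stats::runif(n) < pr_off, "off", "on")
  certainty <- 2 * abs(pr_off - 0.5)              # 0 = guessing, 1 = certain
  conf <- round(1 + 6 * certainty + stats::runif(n, -1, 1))
  battery$judgment <- judgment
  battery$truth_label <- ifelse(battery$truth, "on", "off")
  battery$confidence <- as.integer(pmin(7, pmax(1, conf)))
  battery
}

#' Simulate one judgment
#'
#' Single-trial convenience wrapper around [simulate_judgments()].
#'
#' @param p A `bat_perceiver`.
#' @param trial One-row battery tibble (or a list with `kind`, `magnitude`,
#'   `truth`).
#' @param period_drift_factor Passed to [prob_respond_off()].
#' @return A list with `judgment` and `confidence`.
#' @export
simulate_judgment <- function(p, trial, period_drift_factor = 8) {
  tr <- tibble::tibble(kind = trial$kind, magnitude = trial$magnitude,
                       truth = trial$truth)
  out <- simulate_judgments(p, tr, period_drift_factor)
  list(judgment = out$judgment, confidence = out$confidence)
}

#' Simulate one tapping trial
#'
#' Generates tap onsets from the linear-phase tapper model (see
#' [tapper_params()]): intended taps track the beats at a scaled period
#' with a constant phase offset and Gaussian motor jitter; each intended
#' tap may be dropped, and spurious extra taps are inserted uniformly over
#' the tapped span. Onsets are returned sorted.
#'
#' @param t A `bat_tapper`.
#' @param grid A `bat_grid`.
#' @return Numeric vector of tap onset times in seconds.
#' @export
#' @examples
#' g <- make_beat_grid(120, 8)
#' simulate_taps(tapper_params(), g)  # identical to the beats
simulate_taps <- function(t, grid) {
  stopifnot(inherits(t, "bat_tapper"), inherits(grid, "bat_grid"))
  beats <- grid$beat_onsets
  mibi <- mean_ibi(grid)
  n <- length(beats)
  taps <- beats[1] + t$start_latency + (beats - beats[1]) * t$period_scale +
    t$phase_offset_frac * mibi
  if (t$motor_noise_frac > 0) {
    taps <- taps + stats::rnorm(n, 0, t$motor_noise_frac * mibi)
  }
  if (t$miss_prob > 0) {
    taps <- taps[stats::runif(n) >= t$miss_prob]
  }
  if (t$extra_prob > 0 && length(taps) >= 2) {
    n_extra <- stats::rbinom(1, length(taps), t$extra_prob)
    if (n_extra > 0) {
      taps <- c(taps, stats::runif(n_extra, min(taps), max(taps)))
    }
  }
  sort(taps)
}

# Precomputed geometry for one participant's production block (each test
# excerpt twice): concatenated beats with per-tap trial index, trial first
# beats and mean IBIs. Shared across participants of a cohort.
production_layout <- function(grids, test_ids) {
  ex <- rep(test_ids, each = 2)
  rep_idx <- rep(c(1L, 2L), times = length(test_ids))
  beats_list <- lapply(ex, function(e) grids[[e]]$beat_onsets)
  len <- lengths(beats_list)
  list(ex = ex, rep = rep_idx, n_trials = length(ex),
       beats = unlist(beats_list, use.names = FALSE),
       trial = rep(seq_along(ex), len),
       first = rep(vapply(beats_list, `[`, numeric(1), 1L), len),
       mibi = rep(vapply(ex, function(e) mean_ibi(grids[[e]]),
                         numeric(1)), len))
}

# Draw one participant's full production block in bulk. Statistically
# identical to calling simulate_taps() per trial; the random draws are
# batched (all noise, then misses, then extras) for speed.
bulk_participant_taps <- function(t, lay) {
  taps <- lay$first + t$start_latency +
    (lay$beats - lay$first) * t$period_scale +
    t$phase_offset_frac * lay$mibi
  tid <- lay$trial
  if (t$motor_noise_frac > 0) {
    taps <- taps + stats::rnorm(length(taps), 0, t$motor_noise_frac * lay$mibi)
  }
  if (t$miss_prob > 0) {
    keep <- stats::runif(length(taps)) >= t$miss_prob
    taps <- taps[keep]
    tid <- tid[keep]
  }
  if (t$extra_prob > 0 && length(taps)) {
    cnt <- tabulate(tid, nbins = lay$n_trials)
    n_extra <- stats::rbinom(lay$n_trials, cnt, t$extra_prob)
    for (tr in which(n_extra > 0 & cnt >= 2)) {
      tr_taps <- taps[tid == tr]
      taps <- c(taps, stats::runif(n_extra[tr], min(tr_taps), max(tr_taps)))
      tid <- c(tid, rep(tr, n_extra[tr]))
    }
  }
  ord <- order(tid, taps)
  list(trial = tid[ord], onset = taps[ord])
}

default_param_cols <- function() {
  c(sensitivity = 12, lapse = 0.02, bias = 1.5,
    phase_offset = 0.08, phase_offset_sd = 0.02,
    period_scale = 1, period_scale_sd = 0.005,
    motor_noise = 0.04, motor_noise_sd = 0.01,
    miss_prob = 0.03, extra_prob = 0.01)
}

#' Specify a synthetic cohort design
#'
#' A design couples a cell table -- one row per (group, music bin, dance
#' bin) cell with its sample size and mean perceiver/tapper parameters --
#' with a stimulus battery and a master seed. Any parameter column omitted
#' from `cells` is filled with package defaults; `*_sd` columns give the
#' between-participant SD of the corresponding tapper parameter.
#'
#' Recognised cell columns: `group`, `music_bin`, `dance_bin`, `n`, and the
#' parameters `sensitivity`, `lapse`, `bias`, `phase_offset`,
#' `phase_offset_sd`, `period_scale`, `period_scale_sd`, `motor_noise`,
#' `motor_noise_sd`, `miss_prob`, `extra_prob`.
#'
#' @param cells Data frame with at least `group`, `music_bin`, `dance_bin`
#'   and `n` (all `n >= 0`, at least one positive).
#' @param seed Master integer seed; all randomness in the cohort flows from
#'   it through per-participant substreams, so adding a participant does
#'   not perturb the others.
#' @param excerpts Named list of `bat_grid` objects
#'   (default [default_excerpts()]).
#' @param battery Trial battery (default built from `excerpts` with
#'   [build_battery()] and the master seed).
#' @return An object of class `bat_design`.
#' @export
cohort_design <- function(cells, seed = 1, excerpts = default_excerpts(),
                          battery = NULL) {
  cells <- tibble::as_tibble(cells)
  need <- c("group", "music_bin", "dance_bin", "n")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    stop("`cells` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) == 0 || all(cells$n == 0)) {
    stop("design must contain at least one non-empty cell", call. = FALSE)
  }
  if (any(cells$n < 0)) stop("cell sizes must be >= 0", call. = FALSE)
  defaults <- default_param_cols()
  for (col in names(defaults)) {
    if (!col %in% names(cells)) cells[[col]] <- defaults[[col]]
  }
  if (is.null(battery)) {
    battery <- build_battery(excerpts, seed = seed)
  }
  structure(list(cells = cells, seed = as.integer(seed),
                 excerpts = excerpts, battery = battery),
            class = "bat_design")
}

#' @export
print.bat_design <- function(x, ...) {
  cat(sprintf("<bat_design> %d cells, %d participants, seed %d\n",
              nrow(x$cells), sum(x$cells$n), x$seed))
  invisible(x)
}

#' Default cohort design emulating the study populations
#'
#' Three groups (healthy young adults, healthy older adults, people with
#' early-stage Parkinson's disease) crossed with two music-training bins
#' and two dance-training bins. Parameter means encode the qualitative
#' effects such cohorts show: musically trained participants perceive
#' misalignment more sensitively and tap less variably; untrained
#' Parkinson's patients carry a larger phase offset; older groups tap with
#' more motor noise. Dance training is given no true effect.
#'
#' @param n_per_cell Participants per cell (12 cells).
#' @param seed Master seed for [cohort_design()].
#' @return A `bat_design`.
#' @export
default_cohort_design <- function(n_per_cell = 10, seed = 1) {
  cells <- tidyr::expand_grid(
    group = c("young", "older", "parkinsons"),
    music_bin = c("0-2", "3+"),
    dance_bin = c("0-2", "3+"))
  cells$n <- n_per_cell
  trained <- cells$music_bin == "3+"
  cells$sensitivity <- ifelse(trained, 16, 10)
  cells$bias <- 1.5
  cells$lapse <- 0.02
  cells$phase_offset <- ifelse(cells$group == "parkinsons" & !trained,
                               0.16, 0.08)
  cells$phase_offset_sd <- 0.03
  cells$period_scale <- 1
  cells$period_scale_sd <- 0.006
  cells$motor_noise <- 0.035 +
    0.02 * (cells$group != "young") + ifelse(trained, -0.01, 0.01)
  cells$motor_noise_sd <- 0.008
  cells$miss_prob <- ifelse(cells$group == "parkinsons", 0.05, 0.02)
  cells$extra_prob <- 0.01
  cohort_design(cells, seed = seed)
}

participant_seed <- function(master, index) {
  # deterministic substream per participant, kept inside 32-bit range
  (as.numeric(master) * 7919 + index * 104729) %% 2147483629 + 1
}

draw_years <- function(bin, cutoff = 3) {
  if (startsWith(as.character(bin), "0-")) sample(0:(cutoff - 1), 1)
  else sample(cutoff:(cutoff + 9), 1)
}

age_range <- list(young = c(18, 30), older = c(50, 85),
                  parkinsons = c(50, 85))
age_mean_sd <- list(young = c(20.4, 3.0), older = c(64.6, 9.3),
                    parkinsons = c(68.3, 7.7))

draw_age <- function(group) {
  ms <- age_mean_sd[[group]]
  rng <- age_range[[group]]
  if (is.null(ms)) {
    ms <- c(40, 10)
    rng <- c(18, 90)
  }
  repeat {
    a <- stats::rnorm(1, ms[1], ms[2])
    if (a >= rng[1] && a <= rng[2]) return(round(a, 1))
  }
}

truncate_pos <- function(x, lo = 0) pmax(x, lo)

#' Simulate a full synthetic cohort
#'
#' Generates, for every participant of the design: demographics (age and
#' training years consistent with the cell's bins), perception responses
#' for all test trials of the battery, and production tap records with each
#' excerpt presented twice consecutively. Individual perceiver/tapper
#' parameters are drawn around the cell means. The whole cohort is
#' reproducible from the design's master seed.
#'
#' @param design A `bat_design`.
#' @param tasks Which tasks to simulate (both by default); restricting to
#'   `"production"` skips the perception responses.
#' @return An object of class `bat_cohort`: a list with tibbles
#'   `demographics`, `responses` (one row per test trial), `taps` (one row
#'   per tap), the `grids` and `battery` used, and `truth` (the drawn
#'   per-participant generative parameters, for parameter-recovery checks).
#' @export
#' @examples
#' design <- default_cohort_design(n_per_cell = 2, seed = 42)
#' cohort <- simulate_cohort(design)
#' nrow(cohort$demographics)
simulate_cohort <- function(design, tasks = c("perception", "production")) {
  stopifnot(inherits(design, "bat_design"))
  tasks <- match.arg(tasks, several.ok = TRUE)
  cells <- design$cells
  battery <- design$battery
  test_battery <- battery[battery$phase == "test", ]
  test_ids <- test_battery$excerpt_id
  grids <- design$excerpts
  layout <- production_layout(grids, test_ids)
  n_total <- sum(cells$n)
  pid_width <- max(3, nchar(as.character(n_total)))

  cell_of <- rep(seq_len(nrow(cells)), cells$n)
  pid <- sprintf("P%0*d", pid_width, seq_len(n_total))
  age <- music_years <- dance_years <- numeric(n_total)
  truth_mat <- matrix(NA_real_, n_total, 6,
                      dimnames = list(NULL, c("sensitivity", "bias",
                                              "lapse_rate",
                                              "phase_offset_frac",
                                              "period_scale",
                                              "motor_noise_frac")))
  resp_rows <- vector("list", n_total)
  tap_rows <- vector("list", n_total)
  n_test <- nrow(test_battery)
  for (idx in seq_len(n_total)) {
    cell <- cells[cell_of[idx], ]
    pseed <- participant_seed(design$seed, idx)
    withr::with_seed(pseed, {
      music_years[idx] <- draw_years(cell$music_bin)
      dance_years[idx] <- draw_years(cell$dance_bin)
      age[idx] <- draw_age(cell$group)
      perceiver <- perceiver_params(
        sensitivity = truncate_pos(stats::rnorm(1, cell$sensitivity, 1)),
        lapse_rate = cell$lapse, bias = cell$bias)
      tapper <- tapper_params(
        phase_offset_frac = stats::rnorm(1, cell$phase_offset,
                                         cell$phase_offset_sd),
        period_scale = truncate_pos(
          stats::rnorm(1, cell$period_scale, cell$period_scale_sd), 0.5),
        motor_noise_frac = truncate_pos(
          stats::rnorm(1, cell$motor_noise, cell$motor_noise_sd)),
        miss_prob = cell$miss_prob, extra_prob = cell$extra_prob)
      truth_mat[idx, ] <- c(perceiver$sensitivity, perceiver$bias,
                            perceiver$lapse_rate,
                            tapper$phase_offset_frac, tapper$period_scale,
                            tapper$motor_noise_frac)
      if ("perception" %in% tasks) {
        pr_off <- prob_respond_off(perceiver, test_battery$kind,
                                   test_battery$magnitude)
        judgment <- ifelse(stats::runif(n_test) < pr_off, "off", "on")
        conf <- round(1 + 6 * (2 * abs(pr_off - 0.5)) +
                        stats::runif(n_test, -1, 1))
        resp_rows[[idx]] <- list(judgment = judgment,
                                 confidence = as.integer(
                                   pmin(7, pmax(1, conf))))
      }
      if ("production" %in% tasks) {
        tap_rows[[idx]] <- bulk_participant_taps(tapper, layout)
      }
    })
  }
  demographics <- tibble::tibble(
    participant_id = pid, group = cells$group[cell_of], age = age,
    music_years = music_years, dance_years = dance_years,
    music_bin = cells$music_bin[cell_of],
    dance_bin = cells$dance_bin[cell_of])
  responses <- if ("perception" %in% tasks) {
    tibble::tibble(
      participant_id = rep(pid, each = n_test),
      trial_index = rep(test_battery$trial_index, n_total),
      excerpt_id = rep(test_battery$excerpt_id, n_total),
      kind = rep(test_battery$kind, n_total),
      magnitude = rep(test_battery$magnitude, n_total),
      direction = rep(test_battery$direction, n_total),
      judgment = unlist(lapply(resp_rows, `[[`, "judgment"),
                        use.names = FALSE),
      truth = rep(ifelse(test_battery$truth, "on", "off"), n_total),
      confidence = unlist(lapply(resp_rows, `[[`, "confidence"),
                          use.names = FALSE))
  }
  taps <- if ("production" %in% tasks) {
    n_per <- vapply(tap_rows, function(x) length(x$onset), integer(1))
    trial <- unlist(lapply(tap_rows, `[[`, "trial"), use.names = FALSE)
    tibble::tibble(
      participant_id = rep(pid, n_per),
      excerpt_id = layout$ex[trial],
      repetition = layout$rep[trial],
      tap_onset_s = unlist(lapply(tap_rows, `[[`, "onset"),
                           use.names = FALSE))
  }
  structure(
    list(demographics = demographics, responses = responses, taps = taps,
         truth = tibble::as_tibble(cbind(
           tibble::tibble(participant_id = pid),
           as.data.frame(truth_mat))),
         grids = grids, battery = battery, seed = design$seed),
    class = "bat_cohort"
  )
}

#' @export
print.bat_cohort <- function(x, ...) {
  cat(sprintf(
    "<bat_cohort> %d participants, %d responses, %d taps (seed %d)\n",
    nrow(x$demographics), nrow(x$responses), nrow(x$taps), x$seed))
  invisible(x)
}
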