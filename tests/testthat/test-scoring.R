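test_that("percent correct is plain accuracy on matched labels", {
  expect_equal(percent_correct(rep("on", 17), rep("on", 17)), 100)
  expect_equal(percent_correct(c(rep("on", 12), rep("off", 5)),
                               c(rep("on", 12), rep("on", 5))),
               100 * 12 / 17)
  expect_error(percent_correct(character(), character()), "non-empty")
  expect_error(percent_correct("on", c("on", "off")), "same length")
})

test_that("nearest-beat matching follows the tie rule and the oracle", {
  m <- match_taps_to_beats(0.1, c(0, 0.5))
  expect_equal(m$beat, 0)
  # exact midpoint ties to the earlier beat
  tie <- match_taps_to_beats(0.25, c(0, 0.5))
  expect_equal(tie$beat_index, 1L)
  # taps outside the grid span match the terminal beats
  ends <- match_taps_to_beats(c(-1, 99), c(0, 0.5, 1))
  expect_equal(ends$beat_index, c(1L, 3L))
  expect_error(match_taps_to_beats(numeric(), c(0, 1)), "non-empty")
  expect_error(match_taps_to_beats(0.5, c(1, 0.5)), "strictly increasing")

  withr::with_seed(101, {
    for (i in 1:300) {
      tr <- random_trial()
      got <- match_taps_to_beats(tr$taps, tr$beats)$beat_index
      expect_identical(got, brute_force_match(tr$taps, tr$beats))
    }
  })
})

test_that("asynchrony matches hand computation and perfect-tap zero", {
  beats <- c(0, 0.5, 1)
  expect_equal(asynchrony_score(beats, beats), 0)
  expect_equal(asynchrony_score(beats + 0.05, beats), 0.1)
  expect_equal(asynchrony_score(c(0.1, 0.48, 1.02), beats),
               (0.1 + 0.02 + 0.02) / 3 / 0.5)
})

test_that("CDEV matches its definition in both variants", {
  beats <- c(0, 0.5, 1, 1.5)
  expect_equal(cdev_score(beats, beats), 0)
  expect_equal(cdev_score(c(0, 0.51, 1.02, 1.53), beats), 0.02)
  # IRIs 0.45 and 0.55 with mean IBI 0.5
  taps <- c(0, 0.45, 1.0)
  expect_equal(cdev_score(taps, beats), (0.05 + 0.05) / 2 / 0.5)
  # aggregate variant lets alternating errors cancel
  expect_equal(cdev_score(taps, beats, variant = "aggregate"), 0)
  expect_error(cdev_score(0.3, beats), "at least 2")
})

test_that("CoV matches the sample SD definition and scale invariance", {
  expect_equal(cov_score(c(0, 0.5, 1, 1.5)), 0)
  expect_equal(cov_score(c(0, 0.4, 1.0)), sd(c(0.4, 0.6)) / 0.5)
  t1 <- c(0.1, 0.58, 1.03, 1.62)
  expect_equal(cov_score(t1 * 2), cov_score(t1))
  expect_error(cov_score(c(0, 0.5)), "at least 3")
})

test_that("all production scores are invariant to joint time rescaling", {
  withr::with_seed(202, {
    for (i in 1:50) {
      tr <- random_trial()
      for (c_scale in c(0.5, 2, 7.3)) {
        expect_equal(asynchrony_score(tr$taps * c_scale, tr$beats * c_scale),
                     asynchrony_score(tr$taps, tr$beats))
        expect_equal(cdev_score(tr$taps * c_scale, tr$beats * c_scale),
                     cdev_score(tr$taps, tr$beats))
        expect_equal(cov_score(tr$taps * c_scale), cov_score(tr$taps))
      }
    }
  })
})

test_that("scores ignore tap input order and stay non-negative", {
  withr::with_seed(303, {
    for (i in 1:50) {
      tr <- random_trial()
      perm <- sample(tr$taps)
      expect_equal(asynchrony_score(perm, tr$beats),
                   asynchrony_score(tr$taps, tr$beats))
      expect_equal(cdev_score(perm, tr$beats),
                   cdev_score(tr$taps, tr$beats))
      expect_equal(cov_score(perm), cov_score(tr$taps))
      expect_gte(asynchrony_score(tr$taps, tr$beats), 0)
      expect_gte(cdev_score(tr$taps, tr$beats), 0)
      expect_gte(cov_score(tr$taps), 0)
    }
  })
})

test_that("normalised per-tap asynchrony is at most 0.5 inside the span", {
  withr::with_seed(404, {
    g <- make_beat_grid(runif(1, 60, 160), 20)
    beats <- g$beat_onsets
    for (i in 1:50) {
      taps <- runif(10, min(beats), max(beats))
      m <- match_taps_to_beats(taps, beats)
      expect_true(all(m$abs_diff / mean_ibi(g) <= 0.5 + 1e-12))
    }
  })
})

test_that("trial validation enforces the inclusive minimum tap count", {
  g <- make_beat_grid(120, 10)
  expect_identical(validate_trial(0.5, g)$reason, "too_few_taps")
  expect_true(validate_trial(g$beat_onsets[1:4], g)$valid)   # boundary
  expect_true(validate_trial(g$beat_onsets, g)$valid)
  v <- validate_trial(c(0.1, 0.2, 0.3, 0.4), g, listen_window = 2)
  expect_identical(v$reason, "no_taps_after_window")
})

test_that("invalid trials score as missing, never zero", {
  g <- list(ex = make_beat_grid(120, 10, excerpt_id = "ex"))
  log <- one_trial_log(c(0.5, 1.0), "ex")
  sc <- score_trials(log, g)
  expect_false(sc$valid)
  expect_identical(sc$reason, "too_few_taps")
  expect_true(is.na(sc$asynchrony) && is.na(sc$cdev) && is.na(sc$cov))
})

test_that("score_trials agrees with the single-trial scorers", {
  withr::with_seed(505, {
    grids <- default_excerpts(6)
    logs <- list()
    expected <- list()
    for (i in 1:40) {
      ex <- sample(names(grids), 1)
      g <- grids[[ex]]
      taps <- sort(runif(sample(4:20, 1), 0, g$duration))
      pid <- sprintf("P%02d", i)
      rep_i <- sample(1:2, 1)
      logs[[i]] <- one_trial_log(taps, ex, pid, rep_i)
      expected[[i]] <- tibble::tibble(
        participant_id = pid, excerpt_id = ex, repetition = rep_i,
        asynchrony = oracle_asynchrony(taps, g$beat_onsets),
        cdev = oracle_cdev(taps, g$beat_onsets),
        cov = oracle_cov(taps))
    }
    log <- dplyr::bind_rows(logs)
    exp_tab <- dplyr::arrange(dplyr::bind_rows(expected), participant_id)
    got <- score_trials(log, grids)
    expect_equal(got$asynchrony, exp_tab$asynchrony)
    expect_equal(got$cdev, exp_tab$cdev)
    expect_equal(got$cov, exp_tab$cov)
  })
})

test_that("participant aggregation averages repetitions before excerpts", {
  mk <- function(ex, rep, async, valid = TRUE) {
    tibble::tibble(participant_id = "P1", excerpt_id = ex, repetition = rep,
                   n_taps = 10L, valid = valid,
                   reason = ifelse(valid, NA_character_, "too_few_taps"),
                   asynchrony = ifelse(valid, async, NA_real_),
                   cdev = 0.1, cov = 0.1)
  }
  resp <- tibble::tibble(participant_id = "P1",
                         judgment = rep("on", 4),
                         truth = c("on", "on", "off", "on"))
  # excerpt A reps {0.1, 0.3}, excerpt B reps {0.2, 0.2}: mean of {0.2, 0.2}
  tr <- dplyr::bind_rows(mk("A", 1, 0.1), mk("A", 2, 0.3),
                         mk("B", 1, 0.2), mk("B", 2, 0.2))
  agg <- aggregate_participants(tr, resp)
  expect_equal(agg$asynchrony, 0.2)
  expect_equal(agg$pct_correct, 75)
  expect_equal(agg$n_valid_trials, 4L)

  # a lone valid repetition represents its excerpt
  tr2 <- dplyr::bind_rows(mk("A", 1, 0.1), mk("A", 2, 0, valid = FALSE),
                          mk("B", 1, 0.5), mk("B", 2, 0.5))
  agg2 <- aggregate_participants(tr2, resp)
  expect_equal(agg2$asynchrony, mean(c(0.1, 0.5)))
  expect_equal(agg2$n_valid_trials, 3L)

  # no valid trials: excluded with missing scores
  tr3 <- mk("A", 1, 0, valid = FALSE)
  agg3 <- aggregate_participants(tr3, resp)
  expect_true(agg3$excluded)
  expect_true(is.na(agg3$asynchrony))
})

test_that("uniform trial scores aggregate to the same participant score", {
  co <- withr::with_seed(1, {
    cells <- tibble::tibble(group = "young", music_bin = "0-2",
                            dance_bin = "0-2", n = 1,
                            phase_offset = 0.1, phase_offset_sd = 0,
                            period_scale = 1, period_scale_sd = 0,
                            motor_noise = 0, motor_noise_sd = 0,
                            miss_prob = 0, extra_prob = 0)
    simulate_cohort(cohort_design(cells, seed = 4))
  })
  tab <- score_cohort(co)
  expect_equal(tab$asynchrony, 0.1, tolerance = 1e-10)
  expect_equal(tab$cdev, 0, tolerance = 1e-10)
  expect_equal(tab$n_valid_trials, 34L)
})
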