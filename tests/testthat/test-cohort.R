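test_that("perceiver response model has the right limits", {
  trial_off <- tibble::tibble(kind = "phase", magnitude = 0.175,
                              truth = FALSE)
  # near-infinite sensitivity: always detects an off-beat trial
  sharp <- perceiver_params(sensitivity = 1e6)
  expect_equal(prob_respond_off(sharp, "phase", 0.175), 1)
  withr::with_seed(1, {
    j <- simulate_judgment(sharp, trial_off)
    expect_identical(j$judgment, "off")
  })
  # zero sensitivity, zero bias: coin flip
  guess <- perceiver_params(sensitivity = 0)
  expect_equal(prob_respond_off(guess, "phase", 0.175), 0.5)
  expect_equal(prob_respond_off(guess, "on_beat", 0), 0.5)
  # lapse compresses the range symmetrically
  lapser <- perceiver_params(sensitivity = 1e6, lapse_rate = 0.1)
  expect_equal(prob_respond_off(lapser, "phase", 0.175), 0.9)
  expect_error(perceiver_params(-1), ">= 0")
  expect_error(perceiver_params(1, lapse_rate = 0.7), "0, 0.5")
})

test_that("empirical judgment rate matches the closed-form logistic", {
  p <- perceiver_params(sensitivity = 5)
  target <- plogis(5 * 0.175)
  n <- 10000
  trials <- tibble::tibble(kind = rep("phase", n), magnitude = 0.175,
                           truth = FALSE)
  emp <- withr::with_seed(99, {
    out <- simulate_judgments(p, trials)
    mean(out$judgment == "off")
  })
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(emp - target), 3 * se)
  expect_equal(prob_respond_off(p, "phase", 0.175), target)
})

test_that("period misalignment uses the documented drift factor", {
  p <- perceiver_params(sensitivity = 2, bias = 0)
  expect_equal(prob_respond_off(p, "period", 0.02),
               plogis(2 * 0.02 * 8))
  expect_equal(prob_respond_off(p, "period", 0.02, period_drift_factor = 4),
               plogis(2 * 0.02 * 4))
})

test_that("noiseless tapper parameters are recovered exactly by scoring", {
  g <- make_beat_grid(110, 15)
  # identity tapper reproduces the beats
  expect_equal(simulate_taps(tapper_params(), g), g$beat_onsets)
  # pure period error -> CDEV equals |period_scale - 1|
  taps_p <- simulate_taps(tapper_params(period_scale = 1.02), g)
  expect_equal(cdev_score(taps_p, g), 0.02, tolerance = 1e-12)
  # pure phase offset -> asynchrony equals |phase_offset_frac|
  taps_f <- simulate_taps(tapper_params(phase_offset_frac = 0.05), g)
  expect_equal(asynchrony_score(taps_f, g), 0.05, tolerance = 1e-12)
  expect_equal(cov_score(taps_f), 0)
  expect_error(tapper_params(period_scale = 0), "> 0")
  expect_error(tapper_params(miss_prob = 1), "\\[0, 1\\)")
})

test_that("pure noise yields the folded-normal mean asynchrony", {
  g <- make_beat_grid(120, 20)
  sigma <- 0.05
  n_rep <- 300
  scores <- withr::with_seed(37, {
    vapply(seq_len(n_rep), function(i) {
      asynchrony_score(simulate_taps(
        tapper_params(motor_noise_frac = sigma), g), g)
    }, numeric(1))
  })
  target <- sigma * sqrt(2 / pi)
  se <- sd(scores) / sqrt(n_rep)
  expect_lt(abs(mean(scores) - target), 3 * se)
})

test_that("CoV ignores phase offset and grows with motor noise", {
  g <- make_beat_grid(120, 20)
  res <- withr::with_seed(53, {
    sapply(c(0.01, 0.08), function(sg) {
      mean(vapply(1:100, function(i) {
        off <- sample(c(0, 0.2), 1)   # phase offset varies freely
        cov_score(simulate_taps(
          tapper_params(phase_offset_frac = off, motor_noise_frac = sg), g))
      }, numeric(1)))
    })
  })
  expect_lt(res[1], res[2])
  # and with zero noise the offset leaves CoV at exactly 0
  expect_equal(cov_score(simulate_taps(
    tapper_params(phase_offset_frac = 0.3), g)), 0)
})

test_that("misses and extras change tap counts in the expected direction", {
  g <- make_beat_grid(120, 40)
  withr::with_seed(71, {
    n_miss <- length(simulate_taps(tapper_params(miss_prob = 0.5), g))
    n_extra <- length(simulate_taps(tapper_params(extra_prob = 0.4), g))
  })
  expect_lt(n_miss, 40)
  expect_gt(n_extra, 40)
})

test_that("cohorts have complete batteries and are seed-reproducible", {
  design <- default_cohort_design(n_per_cell = 2, seed = 42)
  co <- simulate_cohort(design)
  n <- nrow(co$demographics)
  expect_equal(n, 2 * 12)
  expect_equal(nrow(co$responses), n * 17)
  trials <- unique(paste(co$taps$participant_id, co$taps$excerpt_id,
                         co$taps$repetition))
  expect_equal(length(trials), n * 34)
  expect_true(all(co$responses$confidence %in% 1:7))
  # training years respect the bins
  tab <- dplyr::inner_join(co$demographics,
                           tibble::tibble(participant_id =
                                            co$demographics$participant_id),
                           by = "participant_id")
  expect_true(all(tab$music_years[tab$music_bin == "0-2"] <= 2))
  expect_true(all(tab$music_years[tab$music_bin == "3+"] >= 3))

  co2 <- simulate_cohort(default_cohort_design(n_per_cell = 2, seed = 42))
  expect_identical(co$taps, co2$taps)
  expect_identical(co$responses, co2$responses)
  expect_identical(co$demographics, co2$demographics)
  co3 <- simulate_cohort(default_cohort_design(n_per_cell = 2, seed = 43))
  expect_false(identical(co$taps, co3$taps))
})

test_that("per-participant substreams survive adding participants", {
  d2 <- default_cohort_design(n_per_cell = 2, seed = 7)
  d3 <- default_cohort_design(n_per_cell = 3, seed = 7)
  co2 <- simulate_cohort(d2)
  co3 <- simulate_cohort(d3)
  # participant 1 exists in both runs with identical data
  p1_2 <- co2$taps[co2$taps$participant_id == "P001", ]
  p1_3 <- co3$taps[co3$taps$participant_id == "P001", ]
  expect_equal(p1_2$tap_onset_s, p1_3$tap_onset_s)
})

test_that("a guessing cohort scores at chance on perception", {
  cells <- tibble::tibble(group = "young", music_bin = "0-2",
                          dance_bin = "0-2", n = 60,
                          sensitivity = 0, bias = 0, lapse = 0)
  co <- simulate_cohort(cohort_design(cells, seed = 77),
                        tasks = "perception")
  pc <- dplyr::summarise(
    dplyr::group_by(co$responses, participant_id),
    pct = percent_correct(judgment, truth))$pct
  n_trials <- 17 * 60
  se <- 100 * sqrt(0.25 / n_trials)
  expect_lt(abs(mean(pc) - 50), 3 * se)
  expect_error(cohort_design(cells[0, ], seed = 1), "non-empty cell")
})
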