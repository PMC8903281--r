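# Shared fixtures and independent oracles for the test suite.

# Exhaustive O(n * m) nearest-beat matcher: the brute-force oracle the
# vectorised matcher is checked against. Ties go to the earlier beat via
# strict improvement (">" keeps the first minimum).
brute_force_match <- function(taps, beats) {
  vapply(taps, function(tp) {
    d <- abs(tp - beats)
    which(d == min(d))[1]
  }, integer(1))
}

# Direct, unoptimised score computations used as oracles.
oracle_asynchrony <- function(taps, beats) {
  mibi <- mean(diff(beats))
  mean(vapply(sort(taps), function(tp) min(abs(tp - beats)), numeric(1))) /
    mibi
}
oracle_cdev <- function(taps, beats) {
  mibi <- mean(diff(beats))
  iri <- diff(sort(taps))
  mean(abs(iri - mibi)) / mibi
}
oracle_cov <- function(taps) {
  iri <- diff(sort(taps))
  sd(iri) / mean(iri)
}

# Random small trial: an irregular grid plus jittered taps.
random_trial <- function() {
  n_beats <- sample(4:12, 1)
  beats <- cumsum(c(runif(1, 0, 1), runif(n_beats - 1, 0.3, 0.9)))
  n_taps <- sample(3:15, 1)
  taps <- runif(n_taps, min(beats) - 0.5, max(beats) + 0.5)
  list(taps = taps, beats = beats)
}

# Tiny deterministic cohort for pipeline tests.
small_cohort <- function(seed = 7, n = 2) {
  simulate_cohort(default_cohort_design(n_per_cell = n, seed = seed))
}

# Tap log tibble for a single trial.
one_trial_log <- function(taps, excerpt_id = "ex", pid = "P1", rep = 1L) {
  tibble::tibble(participant_id = pid, excerpt_id = excerpt_id,
                 repetition = rep, tap_onset_s = taps)
}
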