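# Bayesian model-comparison bookkeeping: posterior model probabilities,
# BF_M, evidence bands, and BIC-approximated Bayes factors for ANOVA-style
# candidate sets.
#
# The bookkeeping arithmetic is exact given a BF_10 column:
#   P(M|data)_i = P(M)_i * BF_10,i / sum_j P(M)_j * BF_10,j
#   BF_M,i      = [P(M|data)_i / (1 - P(M|data)_i)] / [P(M)_i / (1 - P(M)_i)]
# BF_10 values themselves can either be supplied externally (e.g. from a
# published table) or approximated from model fits via BIC:
#   BF_10,i ~= exp((BIC_null - BIC_i) / 2)

#' Posterior model probabilities from priors and Bayes factors
#'
#' @param bf10 Numeric vector of Bayes factors versus the null model, one
#'   per candidate model (the null itself has `bf10 = 1`).
#' @param prior Prior model probabilities, summing to 1; defaults to
#'   uniform.
#' @return Numeric vector of posterior model probabilities, summing to 1.
#' @export
#' @examples
#' posterior_model_probs(c(1, 685845, 46220, 36339, 0.12))
posterior_model_probs <- function(bf10,
                                  prior = rep(1 / length(bf10),
                                              length(bf10))) {
  if (length(bf10) != length(prior)) {
    stop("`bf10` and `prior` must have the same length", call. = FALSE)
  }
  if (any(bf10 < 0) || any(!is.finite(bf10))) {
    stop("`bf10` values must be finite and >= 0", call. = FALSE)
  }
  if (abs(sum(prior) - 1) > 1e-9 || any(prior < 0)) {
    stop("`prior` must be non-negative and sum to 1", call. = FALSE)
  }
  w <- prior * bf10
  total <- sum(w)
  if (total == 0) {
    stop("all prior-weighted Bayes factors are zero", call. = FALSE)
  }
  w / total
}

#' Change from prior to posterior model odds (BF_M)
#'
#' The relative likelihood of one model compared with the average of all
#' other models: its posterior odds divided by its prior odds.
#'
#' @param prior,posterior Prior and posterior model probabilities, both
#'   strictly inside (0, 1) (degenerate probabilities give unbounded or
#'   undefined odds). Vectorised.
#' @return Numeric vector of BF_M values.
#' @export
#' @examples
#' bf_m(0.2, 0.5)  # posterior odds 1 over prior odds 0.25 = 4
bf_m <- function(prior, posterior) {
  if (any(prior <= 0 | prior >= 1)) {
    stop("`prior` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(posterior <= 0 | posterior >= 1)) {
    stop("`posterior` must lie strictly in (0, 1): degenerate ",
         "probabilities give unbounded odds", call. = FALSE)
  }
  (posterior / (1 - posterior)) / (prior / (1 - prior))
}

#' Classify a Bayes factor into an evidence band
#'
#' Bands follow the conventional breakpoints 0.1, 0.33, 3 and 10:
#' `BF_10 < 0.1` strong support for the null, up to 0.33 moderate support
#' for the null, 0.33-3 insufficient to support either hypothesis, 3-10
#' moderate support for the alternative, above 10 strong support for the
#' alternative. Values falling exactly on a breakpoint are assigned to the
#' weaker (more conservative) band.
#'
#' @param bf10 Positive numeric vector of Bayes factors versus the null.
#' @return Factor with levels `strong_null`, `moderate_null`,
#'   `insufficient`, `moderate_alt`, `strong_alt`.
#' @export
#' @examples
#' classify_evidence(c(0.17, 0.5, 685845))
classify_evidence <- function(bf10) {
  if (any(!is.finite(bf10) | bf10 <= 0)) {
    stop("`bf10` must be positive and finite", call. = FALSE)
  }
  labels <- c("strong_null", "moderate_null", "insufficient",
              "moderate_alt", "strong_alt")
  band <- ifelse(bf10 < 0.1, "strong_null",
          ifelse(bf10 < 0.33, "moderate_null",
          ifelse(bf10 <= 3, "insufficient",
          ifelse(bf10 <= 10, "moderate_alt", "strong_alt"))))
  factor(band, levels = labels)
}

#' Assemble a model-comparison table
#'
#' Combines model names, priors and BF_10 values into the standard
#' model-comparison layout with posterior probabilities, BF_M and evidence
#' bands. The null model must be present with `bf10 = 1`.
#'
#' @param model Character vector of model labels; one must be `"null"`.
#' @param bf10 Bayes factors versus the null model.
#' @param prior Prior model probabilities (default uniform).
#' @return A tibble with columns `model`, `prior_prob`, `posterior_prob`,
#'   `bf_m`, `bf10`, `evidence` (BF_M is `NA` where a posterior of exactly
#'   0 or 1 makes the odds degenerate).
#' @export
#' @examples
#' bayes_model_table(
#'   c("null", "music", "music + group + music:group", "music + group",
#'     "group"),
#'   c(1, 685845, 46220, 36339, 0.12))
bayes_model_table <- function(model, bf10,
                              prior = rep(1 / length(bf10), length(bf10))) {
  if (length(model) != length(bf10)) {
    stop("`model` and `bf10` must have the same length", call. = FALSE)
  }
  if (!"null" %in% model) {
    stop("the candidate set must include the null model (label \"null\")",
         call. = FALSE)
  }
  if (abs(bf10[model == "null"] - 1) > 1e-12) {
    stop("the null model must have bf10 = 1", call. = FALSE)
  }
  posterior <- posterior_model_probs(bf10, prior)
  ok <- posterior > 0 & posterior < 1 & prior > 0 & prior < 1
  bfm <- rep(NA_real_, length(bf10))
  bfm[ok] <- bf_m(prior[ok], posterior[ok])
  evidence <- factor(rep(NA_character_, length(bf10)),
                     levels = levels(classify_evidence(1)))
  pos <- bf10 > 0
  evidence[pos] <- classify_evidence(bf10[pos])
  tibble::tibble(model = model, prior_prob = prior,
                 posterior_prob = posterior, bf_m = bfm, bf10 = bf10,
                 evidence = evidence)
}

#' BIC-approximated Bayes factors from fitted models
#'
#' Approximates each model's Bayes factor against the null with
#' `exp((BIC_null - BIC_i) / 2)`, the unit-information-prior approximation.
#' This is a deliberate approximation: it will not numerically match Bayes
#' factors computed under other prior choices (e.g. JASP's default
#' multivariate Cauchy priors), but it preserves their ordering and
#' order of magnitude for moderate-to-large samples.
#'
#' @param fits Named list of fitted models supporting [stats::BIC()]; one
#'   element must be named `"null"` (the intercept-only or grouping-free
#'   model).
#' @return Named numeric vector of BF_10 values in the input order, with
#'   the null model's value exactly 1.
#' @export
bf10_from_fits <- function(fits) {
  if (!is.list(fits) || is.null(names(fits)) || !"null" %in% names(fits)) {
    stop("`fits` must be a named list containing a \"null\" model",
         call. = FALSE)
  }
  bics <- vapply(fits, stats::BIC, numeric(1))
  bf <- exp((bics[["null"]] - bics) / 2)
  bf[["null"]] <- 1
  bf
}

#' Bayesian ANOVA via BIC model comparison
#'
#' Builds the standard candidate set for one or two factors -- null, each
#' main effect, the additive model, and the full model with interaction --
#' fits each by least squares, and converts BICs into an approximate
#' model-comparison table. Rows with missing values are dropped listwise.
#'
#' @inheritParams factorial_anova
#' @param prior Prior model probabilities over the candidate set (default
#'   uniform).
#' @return A [bayes_model_table()] tibble; attribute `n_used` records the
#'   sample size.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_design(5, seed = 3))
#' tab <- score_cohort(cohort)
#' bayes_anova(tab, "pct_correct", c("music_bin", "group"))
bayes_anova <- function(data, dv, factors, prior = NULL) {
  stopifnot(length(factors) %in% c(1L, 2L))
  d <- as.data.frame(data)
  keep <- stats::complete.cases(d[, c(dv, factors), drop = FALSE])
  d <- d[keep, , drop = FALSE]
  for (f in factors) d[[f]] <- droplevels(factor(d[[f]]))
  terms_list <- if (length(factors) == 1) {
    stats::setNames(list("1", factors[1]), c("null", factors[1]))
  } else {
    a <- factors[1]
    b <- factors[2]
    stats::setNames(
      list("1", a, b, paste(a, "+", b),
           paste0(a, " + ", b, " + ", a, ":", b)),
      c("null", a, b, paste(a, "+", b),
        paste0(a, " + ", b, " + ", a, ":", b)))
  }
  fits <- lapply(terms_list, function(rhs) {
    stats::lm(stats::as.formula(paste(dv, "~", rhs)), data = d)
  })
  bf <- bf10_from_fits(fits)
  if (is.null(prior)) prior <- rep(1 / length(bf), length(bf))
  out <- bayes_model_table(names(bf), unname(bf), prior)
  attr(out, "n_used") <- nrow(d)
  out
}

#' Bundled reference model-comparison tables
#'
#' Eight model-comparison tables from a large published BAT study of music
#' and dance training across healthy young adults, healthy older adults
#' and people with early-stage Parkinson's disease (N = 458): for each of
#' the four outcome measures (percent correct, asynchrony, CDEV, CoV), one
#' five-model comparison over music training and group, and one over dance
#' training and group. Columns give the printed prior probability,
#' posterior probability, BF_M and BF_10 of every model. These tables
#' exercise the bookkeeping arithmetic: feeding each BF_10 column and
#' uniform priors into [bayes_model_table()] reproduces the posterior
#' column.
#'
#' @return A tibble with columns `table_id`, `outcome`, `factor_set`,
#'   `model`, `p_m`, `p_m_data`, `bf_m`, `bf10`.
#' @export
bat_reference_tables <- function() {
  path <- system.file("extdata", "reference_bayes_tables.csv",
                      package = "batkit", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    table_id = readr::col_character(),
                    outcome = readr::col_character(),
                    factor_set = readr::col_character(),
                    model = readr::col_character(),
                    p_m = readr::col_double(),
                    p_m_data = readr::col_double(),
                    bf_m = readr::col_double(),
                    bf10 = readr::col_double()))
}
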