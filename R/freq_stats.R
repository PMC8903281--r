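# Group-level frequentist analysis: training binning, Type III factorial
# ANOVA with partial eta squared, simple main effects, Bonferroni pairwise
# comparisons, Welch t tests and age-score regressions.

#' Bin years of training into low/high categories
#'
#' The standard split is 0-2 versus 3+ years, chosen to separate minimal
#' from more extensive training while keeping group sizes workable; a
#' stricter cutoff (e.g. 6, giving 0-5 vs 6+) is supported for sensitivity
#' analyses.
#'
#' @param years Non-negative numeric vector of training years.
#' @param cutoff Integer cutoff; years below it fall in the low bin.
#' @return A factor with levels like `"0-2"` and `"3+"` (labels follow the
#'   cutoff).
#' @export
#' @examples
#' categorize_training(c(0, 2, 3, 10))
#' categorize_training(5, cutoff = 6)  # "0-5"
categorize_training <- function(years, cutoff = 3) {
  if (any(is.na(years)) || any(years < 0)) {
    stop("`years` must be non-negative and non-missing", call. = FALSE)
  }
  if (cutoff < 1) stop("`cutoff` must be >= 1", call. = FALSE)
  low <- paste0("0-", cutoff - 1)
  high <- paste0(cutoff, "+")
  factor(ifelse(years < cutoff, low, high), levels = c(low, high))
}

drop_missing_dv <- function(data, dv, vars) {
  keep <- stats::complete.cases(data[, c(dv, vars), drop = FALSE])
  list(data = data[keep, , drop = FALSE], n_dropped = sum(!keep))
}

#' Factorial ANOVA with Type III sums of squares and partial eta squared
#'
#' Fits a full-factorial fixed-effects linear model (optionally with
#' additive continuous covariates, i.e. an ANCOVA) under sum-to-zero
#' contrasts and reports Type III tests -- the appropriate choice for the
#' highly unbalanced cells typical of convenience samples. Rows with a
#' missing outcome or factor are dropped listwise.
#'
#' @param data Participant-level data frame (e.g. from [score_cohort()]).
#' @param dv Name of the outcome column.
#' @param factors Character vector of factor column names (crossed with all
#'   interactions).
#' @param covariates Optional character vector of continuous covariates
#'   entered additively (no interactions with factors).
#' @return A tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `sum_sq`, `F`, `p`, `eta_p2` (partial eta squared,
#'   `SS_effect / (SS_effect + SS_error)`). Attributes `n_used` and
#'   `n_dropped` record the listwise deletion.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_design(5, seed = 2))
#' tab <- score_cohort(cohort)
#' factorial_anova(tab, "pct_correct", c("group", "music_bin"))
factorial_anova <- function(data, dv, factors, covariates = character()) {
  stopifnot(length(factors) >= 1)
  cols <- c(factors, covariates)
  missing_cols <- setdiff(c(dv, cols), names(data))
  if (length(missing_cols)) {
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cleaned <- drop_missing_dv(as.data.frame(data), dv, cols)
  d <- cleaned$data
  for (f in factors) {
    d[[f]] <- droplevels(factor(d[[f]]))
    if (nlevels(d[[f]]) < 2) {
      stop(sprintf("factor `%s` has fewer than 2 levels after deletion", f),
           call. = FALSE)
    }
  }
  if (length(factors) > 1) {
    cell_tab <- table(d[factors])
    if (any(cell_tab == 0)) {
      empty <- which(cell_tab == 0, arr.ind = TRUE)
      lab <- apply(empty, 1, function(ix) {
        paste(mapply(function(f, i) dimnames(cell_tab)[[f]][i],
                     seq_along(factors), ix),
              collapse = " x ")
      })
      stop("interaction inestimable: empty cell(s) ",
           paste(lab, collapse = "; "), call. = FALSE)
    }
  }
  rhs <- c(covariates, paste(factors, collapse = " * "))
  form <- stats::reformulate(rhs, response = dv)
  contr <- stats::setNames(
    replicate(length(factors), "contr.sum", simplify = FALSE), factors)
  if (stats::sd(d[[dv]]) == 0) {
    # constant outcome: every effect explains nothing; define F = 0, p = 1
    labels <- attr(stats::terms(form), "term.labels")
    df_num <- vapply(labels, function(lb) {
      parts <- strsplit(lb, ":", fixed = TRUE)[[1]]
      prod(vapply(parts, function(p) {
        if (p %in% factors) nlevels(d[[p]]) - 1L else 1L
      }, numeric(1)))
    }, numeric(1))
    out <- tibble::tibble(effect = labels, df_num = df_num,
                          df_den = nrow(d) - sum(df_num) - 1,
                          sum_sq = 0, F = 0, p = 1, eta_p2 = 0)
    attr(out, "n_used") <- nrow(d)
    attr(out, "n_dropped") <- cleaned$n_dropped
    return(out)
  }
  fit <- stats::lm(form, data = d, contrasts = contr)
  av <- car::Anova(fit, type = 3)
  av <- as.data.frame(av)
  ss_err <- av["Residuals", "Sum Sq"]
  df_den <- av["Residuals", "Df"]
  keep <- !rownames(av) %in% c("(Intercept)", "Residuals")
  eff <- av[keep, , drop = FALSE]
  ss <- eff[["Sum Sq"]]
  eta <- ifelse(ss + ss_err > 0, ss / (ss + ss_err), 0)
  fstat <- eff[["F value"]]
  pval <- eff[["Pr(>F)"]]
  # constant outcome: define F = 0, p = 1 rather than 0/0
  degenerate <- !is.finite(fstat) & ss == 0
  fstat[degenerate] <- 0
  pval[degenerate] <- 1
  out <- tibble::tibble(
    effect = rownames(eff), df_num = eff$Df, df_den = df_den,
    sum_sq = ss, F = fstat, p = pval, eta_p2 = eta)
  attr(out, "n_used") <- nrow(d)
  attr(out, "n_dropped") <- cleaned$n_dropped
  out
}

#' Simple main effects of one factor within levels of another
#'
#' Follow-up to a significant interaction: a one-way ANOVA of
#' `across_factor` is run separately within each level of `within_factor`,
#' each with its own F, degrees of freedom, p and partial eta squared.
#'
#' @inheritParams factorial_anova
#' @param within_factor Factor whose levels define the strata.
#' @param across_factor Factor tested within each stratum.
#' @return A tibble with one row per stratum: `level` plus the
#'   [factorial_anova()] columns.
#' @export
simple_main_effects <- function(data, dv, within_factor, across_factor) {
  data <- as.data.frame(data)
  levels_within <- unique(as.character(data[[within_factor]]))
  rows <- lapply(sort(levels_within), function(lev) {
    sub <- data[data[[within_factor]] == lev, , drop = FALSE]
    res <- factorial_anova(sub, dv, across_factor)
    dplyr::bind_cols(tibble::tibble(level = lev), res)
  })
  dplyr::bind_rows(rows)
}

#' Bonferroni-corrected pairwise comparisons between cell means
#'
#' Compares every pair of cells (levels of one factor, or of the
#' interaction of several) with Welch two-sample t tests and applies the
#' Bonferroni correction `p_adj = min(1, p * m)` over the `m` comparisons.
#'
#' @inheritParams factorial_anova
#' @param cell_factors Character vector of factor columns whose combination
#'   defines the cells.
#' @return A tibble with one row per pair: `cell_a`, `cell_b`, `mean_a`,
#'   `mean_b`, `diff`, `t`, `df`, `p`, `p_adj`, `m`.
#' @export
bonferroni_pairwise <- function(data, dv, cell_factors) {
  data <- as.data.frame(data)
  keep <- !is.na(data[[dv]])
  for (f in cell_factors) keep <- keep & !is.na(data[[f]])
  data <- data[keep, , drop = FALSE]
  cell <- interaction(data[cell_factors], sep = ":", drop = TRUE)
  levs <- levels(cell)
  if (length(levs) < 2) stop("need at least 2 cells", call. = FALSE)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    xa <- data[[dv]][cell == pr[1]]
    xb <- data[[dv]][cell == pr[2]]
    tt <- welch_t(xa, xb)
    tibble::tibble(cell_a = pr[1], cell_b = pr[2],
                   mean_a = mean(xa), mean_b = mean(xb),
                   diff = mean(xa) - mean(xb),
                   t = tt$t, df = tt$df, p = tt$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, out$p * m)
  out$m <- m
  out
}

#' Welch unequal-variance two-sample t test
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @return A list with `t`, `df` (Satterthwaite), `p` (two-sided),
#'   `mean_x`, `mean_y`.
#' @seealso [welch_t_summary()] for summary-statistic input.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample must contain at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: no variance anywhere; t is 0 if means agree else undefined
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    stop("both samples are constant with different means", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Welch t test from summary statistics
#'
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Sample means, SDs and sizes.
#' @return As [welch_t()].
#' @export
#' @examples
#' welch_t_summary(64.63, 9.27, 139, 68.28, 7.73, 41)
welch_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  if (n_x < 2 || n_y < 2) {
    stop("each sample must contain at least 2 observations", call. = FALSE)
  }
  vx <- sd_x^2 / n_x
  vy <- sd_y^2 / n_y
  se <- sqrt(vx + vy)
  t <- (mean_x - mean_y) / se
  df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_x = mean_x, mean_y = mean_y)
}

#' Linear model of a score on age
#'
#' Ordinary least squares of the outcome on age (or another continuous
#' predictor), used to check whether age differences between groups could
#' drive score differences.
#'
#' @inheritParams factorial_anova
#' @param predictor Name of the continuous predictor column.
#' @return A list with `slope`, `se`, `t`, `p`, `r_squared`, `n`.
#' @export
age_score_model <- function(data, dv, predictor = "age") {
  data <- as.data.frame(data)
  keep <- stats::complete.cases(data[, c(dv, predictor)])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 complete rows", call. = FALSE)
  if (stats::sd(d[[predictor]]) == 0) {
    stop(sprintf("`%s` has zero variance", predictor), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(predictor, response = dv), data = d)
  co <- summary(fit)$coefficients
  if (nrow(co) < 2) {  # constant dv: slope estimated as exactly 0
    return(list(slope = 0, se = NA_real_, t = NA_real_, p = NA_real_,
                r_squared = 0, n = nrow(d)))
  }
  list(slope = unname(co[2, 1]), se = unname(co[2, 2]),
       t = unname(co[2, 3]), p = unname(co[2, 4]),
       r_squared = summary(fit)$r.squared, n = nrow(d))
}
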