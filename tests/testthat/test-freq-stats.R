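test_that("training years bin at the cutoff, inclusive above", {
  expect_equal(as.character(categorize_training(c(0, 2, 3, 12))),
               c("0-2", "0-2", "3+", "3+"))
  expect_equal(as.character(categorize_training(5, cutoff = 6)), "0-5")
  expect_equal(as.character(categorize_training(6, cutoff = 6)), "6+")
  expect_error(categorize_training(-1), "non-negative")
})

test_that("two balanced groups give the F = t^2 identity", {
  withr::with_seed(11, {
    d <- tibble::tibble(g = rep(c("a", "b"), each = 25),
                        y = rnorm(50) + rep(c(0, 0.4), each = 25))
  })
  a <- factorial_anova(d, "y", "g")
  t2 <- t.test(y ~ g, data = d, var.equal = TRUE)$statistic^2
  expect_equal(a$F, unname(t2), tolerance = 1e-8)
  expect_equal(a$df_num, 1)
  expect_equal(a$df_den, 48)
})

test_that("constant outcome yields zero F and effect size", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 5),
                      h = rep(c("x", "y"), 5), y = 1)
  a <- factorial_anova(d, "y", c("g", "h"))
  expect_true(all(a$F == 0))
  expect_true(all(a$eta_p2 == 0))
  expect_true(all(a$p == 1))
})

test_that("Type III results are invariant to row and level order", {
  withr::with_seed(21, {
    d <- tibble::tibble(
      g = sample(c("young", "older", "parkinsons"), 90, TRUE,
                 prob = c(0.6, 0.3, 0.1)),
      m = sample(c("0-2", "3+"), 90, TRUE),
      y = rnorm(90))
    d$y <- d$y + (d$g == "older") * 0.5 + (d$m == "3+") * 0.3
    a1 <- factorial_anova(d, "y", c("g", "m"))
    d2 <- d[sample(nrow(d)), ]
    d2$g <- factor(d2$g, levels = c("parkinsons", "young", "older"))
    a2 <- factorial_anova(d2, "y", c("g", "m"))
    expect_equal(a1$F, a2$F, tolerance = 1e-10)
    expect_equal(a1$p, a2$p, tolerance = 1e-10)
    expect_true(all(a1$eta_p2 >= 0 & a1$eta_p2 <= 1))
    expect_true(all(a1$p >= 0 & a1$p <= 1))
  })
})

test_that("empty design cells raise an inestimable-effect error by name", {
  d <- tibble::tibble(g = c("a", "a", "b", "b"),
                      m = c("x", "x", "x", "x"),
                      y = rnorm(4))
  expect_error(factorial_anova(d, "y", c("g", "m")), "fewer than 2 levels")
  d2 <- tibble::tibble(g = c("a", "a", "b", "b", "a", "b"),
                       m = c("x", "y", "x", "x", "x", "x"),
                       y = rnorm(6))
  expect_error(factorial_anova(d2, "y", c("g", "m")), "empty cell.*b x y")
})

test_that("listwise deletion is recorded", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 10), y = rnorm(20))
  d$y[c(1, 5)] <- NA
  a <- factorial_anova(d, "y", "g")
  expect_equal(attr(a, "n_used"), 18)
  expect_equal(attr(a, "n_dropped"), 2)
})

test_that("ANCOVA covariates are entered additively", {
  withr::with_seed(31, {
    d <- tibble::tibble(g = rep(c("a", "b"), each = 30),
                        age = runif(60, 20, 70))
    d$y <- 0.02 * d$age + (d$g == "b") * 0.5 + rnorm(60, 0, 0.3)
  })
  a <- factorial_anova(d, "y", "g", covariates = "age")
  expect_setequal(a$effect, c("age", "g"))
  expect_true(all(a$p < 0.05))
})

test_that("simple main effects reduce to per-stratum one-way tests", {
  withr::with_seed(41, {
    d <- tibble::tibble(
      g = rep(c("young", "parkinsons"), each = 40),
      m = rep(c("0-2", "3+"), 40),
      y = rnorm(80))
    # effect of m only within parkinsons
    d$y[d$g == "parkinsons" & d$m == "3+"] <-
      d$y[d$g == "parkinsons" & d$m == "3+"] + 2
  })
  sme <- simple_main_effects(d, "y", "g", "m")
  expect_equal(nrow(sme), 2)
  pd <- sme[sme$level == "parkinsons", ]
  yg <- sme[sme$level == "young", ]
  expect_lt(pd$p, 0.001)
  expect_gt(yg$p, 0.05)
  # stratum F equals the squared pooled t in that stratum
  sub <- d[d$g == "young", ]
  t2 <- t.test(y ~ m, data = sub, var.equal = TRUE)$statistic^2
  expect_equal(yg$F, unname(t2), tolerance = 1e-8)
})

test_that("Bonferroni adjustment is capped, monotone and >= raw p", {
  withr::with_seed(51, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 15),
                        y = rnorm(45) + rep(c(0, 0, 1), each = 15))
  })
  pw <- bonferroni_pairwise(d, "y", "g")
  expect_equal(nrow(pw), 3)
  expect_equal(pw$m, rep(3, 3))
  expect_true(all(pw$p_adj >= pw$p))
  expect_true(all(pw$p_adj <= 1))
  expect_equal(pw$p_adj, pmin(1, pw$p * 3))
  expect_equal(order(pw$p_adj), order(pw$p))
})

test_that("Welch t matches R's t.test and the summary-statistic formula", {
  withr::with_seed(61, {
    x <- rnorm(30, 0, 1)
    y <- rnorm(12, 0.8, 2)
  })
  ours <- welch_t(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value)
  # summary-statistic path agrees with the raw path on exact moments
  summ <- welch_t_summary(mean(x), sd(x), length(x),
                          mean(y), sd(y), length(y))
  expect_equal(summ$t, ours$t, tolerance = 1e-12)
  expect_equal(summ$df, ours$df, tolerance = 1e-12)
  expect_identical(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("group age contrast from published summary moments is ~ -2.5", {
  res <- welch_t_summary(64.63, 9.27, 139, 68.28, 7.73, 41)
  expect_lt(abs(res$t - (-2.5)), 0.1)
  expect_lt(res$p, 0.05)
})

test_that("age-score regression recovers exact linear relations", {
  d <- tibble::tibble(age = c(20, 30, 40, 55, 70))
  d$y <- 2 * d$age
  fit <- suppressWarnings(age_score_model(d, "y"))  # exact fit warns
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  d$z <- 5
  expect_equal(suppressWarnings(age_score_model(d, "z"))$slope, 0,
               tolerance = 1e-12)
  d$age <- 10
  expect_error(age_score_model(d, "y"), "zero variance")
})
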