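# Collagen degradation: OLS fit, slope-ratio criterion, weekly group tests.

test_that("OLS recovers a perfect line exactly and matches the two-point closed form", {
  t <- 1:12
  fit <- suppressWarnings(fit_linear_degradation(t, 0.42 - 0.006 * t))
  expect_equal(fit$k, -0.006, tolerance = 1e-12)
  expect_equal(fit$b, 0.42, tolerance = 1e-12)
  expect_true(fit$ci_k[1] <= fit$k && fit$k <= fit$ci_k[2])

  # two distinct time points: slope = rise/run
  fit2 <- suppressWarnings(
    fit_linear_degradation(c(0, 0, 10, 10), c(0.4, 0.4, 0.3, 0.3)))
  expect_equal(fit2$k, -0.01)
  expect_equal(fit2$b, 0.4)

  expect_error(fit_linear_degradation(c(1, 1, 1), c(0.1, 0.2, 0.3)), "unidentifiable")
  expect_error(fit_linear_degradation(1:2, c(0.1, 0.2)), "at least 3")
})

test_that("OLS residuals are orthogonal to time and the fit is affine-equivariant in time", {
  set.seed(21)
  t <- rep(1:12, 5)
  y <- 0.43 - 0.004 * t + rnorm(length(t), 0, 0.01)
  fit <- fit_linear_degradation(t, y)
  resid <- y - (fit$b + fit$k * t)
  expect_lt(abs(sum(resid * t)), 1e-8)
  # shifting/scaling time reparameterizes coefficients exactly
  fit_shift <- fit_linear_degradation(2 * t + 3, y)
  expect_equal(fit_shift$k, fit$k / 2, tolerance = 1e-10)
  expect_equal(fit_shift$b + fit_shift$k * 3, fit$b, tolerance = 1e-10)
})

test_that("slope ratio separates photoaging-like decline and withholds on sign discordance", {
  mk_fit <- function(k, b, se = 5e-4) {
    structure(list(k = k, b = b, se_k = se, se_b = se,
                   ci_k = k + c(-2, 2) * se, ci_b = b + c(-2, 2) * se,
                   p_k = 1e-4, p_b = 1e-4, n = 100),
              class = "degradation_fit")
  }
  ctrl <- mk_fit(-0.003, 0.431)
  photo <- mk_fit(-0.006, 0.420)
  r <- slope_ratio(ctrl, photo)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$photoaging_like, "b")  # the control rate is about half

  same <- slope_ratio(ctrl, ctrl)
  expect_equal(same$ratio, 1)
  expect_equal(same$classification, "indistinguishable")

  disc <- slope_ratio(mk_fit(0.003, 0.4), photo)
  expect_true("sign_discordant" %in% disc$flags)
  expect_true(is.na(disc$classification))
  expect_error(slope_ratio(ctrl, mk_fit(0, 0.4)), "zero")
})

test_that("exact Mann-Whitney p-values match full enumeration for combined n <= 10", {
  # spec-style constructed case: fully separated triples
  expect_equal(mann_whitney_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(33)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney_p(x, y), enumerate_mw_p(x, y), tolerance = 1e-12)
  }
  # identical samples in both groups -> p = 1
  expect_equal(mann_whitney_p(c(1, 2, 3, 7), c(1, 2, 3, 7)), 1)
})

test_that("weekly group comparison reports per-week tests and skips empty weeks", {
  cfg <- cohort_config(n_photoaging = 8, n_control = 8,
                       withdrawal_n = c(photoaging = 0, control = 0),
                       mortality_hazard = 0, seed = 6)
  co <- simulate_cohort(cfg)
  tab <- weekly_group_comparison(co, "eta_collagen")
  expect_equal(tab$week, 1:12)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # diverging lines: late weeks should separate
  expect_lt(tab$p_value[12], 0.05)

  co_gap <- co[!(co$week == 7 & co$group == "control"), ]
  expect_warning(weekly_group_comparison(co_gap, "eta_collagen"), "week 7 skipped")
})

test_that("normality check behaves as a Shapiro-Wilk wrapper with guards", {
  expect_error(normality_check(rep(0.4, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "\\[3, 5000\\]")
  set.seed(12)
  # heavily skewed samples are rejected far above the nominal rate
  rej <- mean(replicate(200, normality_check(rexp(50))$p_value < 0.05))
  expect_gt(rej, 0.5)
  ok <- normality_check(rnorm(50))
  expect_true(ok$statistic > 0 && ok$statistic <= 1)
})

test_that("slope CIs attain nominal coverage under the regression model's assumptions", {
  # iid errors (between-animal SD zero, no attrition): coverage ~95%
  cfg_fn <- function() cohort_config(
    n_photoaging = 2, n_control = 10, noise_sd_between = 0,
    withdrawal_n = c(photoaging = 0, control = 0),
    mortality_hazard = 0, seed = 1)
  cfg <- cfg_fn()
  n_rep <- 300
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(cfg, seed = 5000 + r)
    obs <- observed_rows(co)
    obs <- obs[obs$group == "control", ]
    fit <- fit_linear_degradation(obs$week, obs$eta_collagen)
    cover[r] <- fit$ci_k[1] <= -0.003 && -0.003 <= fit$ci_k[2]
  }
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})

test_that("degradation report combines fits, weekly tests, and the ratio criterion", {
  co <- simulate_cohort(cohort_config(seed = 14))
  rep <- degradation_report(co)
  expect_named(rep$fits, c("control", "photoaging"))
  expect_lt(rep$fits$photoaging$k, 0)
  expect_true(is.finite(rep$ratio$ratio))
})
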