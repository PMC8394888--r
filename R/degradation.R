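# Collagen degradation rate: eta_collagen(t) = k*t + b fitted by ordinary
# least squares on pooled animal-week means, with the slope ratio between
# groups as the photoaging-vs-chronoaging criterion.

#' Fit the linear collagen-degradation model
#'
#' Ordinary least squares of eta on time in weeks, `eta = k*t + b`, with
#' standard errors, 95% two-sided confidence intervals (t-distribution,
#' n - 2 df) and coefficient p-values. One observation is one animal-week
#' mean (the five-site average); censored animals contribute the weeks
#' observed before withdrawal or death.
#'
#' @param times numeric, time in weeks (first measurement week = 1 by the
#'   cohort convention; the fit itself is origin-agnostic).
#' @param values numeric eta observations, same length.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return list of class `degradation_fit` with `k`, `b`, `se_k`, `se_b`,
#'   `ci_k`, `ci_b`, `p_k`, `p_b`, `n`, and the underlying `lm` fit.
#' @export
fit_linear_degradation <- function(times, values, conf_level = 0.95) {
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (length(times) < 3) stop("fit_linear_degradation: need at least 3 observations")
  if (length(unique(times)) < 2)
    stop("fit_linear_degradation: all times identical, slope unidentifiable")
  if (length(unique(times)) < 3)
    warning("fit_linear_degradation: only 2 distinct time points; fit is exact interpolation")
  fit <- stats::lm(values ~ times)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  structure(list(
    k = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
    se_k = sm["times", "Std. Error"], se_b = sm["(Intercept)", "Std. Error"],
    ci_k = unname(ci["times", ]), ci_b = unname(ci["(Intercept)", ]),
    p_k = sm["times", "Pr(>|t|)"], p_b = sm["(Intercept)", "Pr(>|t|)"],
    n = length(times), lm_fit = fit),
    class = "degradation_fit")
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat(sprintf(
    "<degradation_fit> eta = %.4f %+.4f * t  (n = %d)\n  k: se %.4f, 95%% CI [%.4f, %.4f], p = %.3g\n  b: se %.4f, 95%% CI [%.4f, %.4f], p = %.3g\n",
    x$b, x$k, x$n, x$se_k, x$ci_k[1], x$ci_k[2], x$p_k,
    x$se_b, x$ci_b[1], x$ci_b[2], x$p_b))
  invisible(x)
}

#' Slope ratio and photoaging classification
#'
#' Compares two fitted degradation rates as the ratio `k_a / k_b`. The
#' steeper-declining group is labelled `"photoaging-like"` when (i) both
#' slopes are significantly negative (95% CI entirely below 0) and (ii) the
#' ratio departs from 1 beyond the configurable bounds (default
#' \[2/3, 3/2\]). With sign-discordant slopes the classification is withheld
#' and a diagnostic flag raised.
#'
#' @param fit_a,fit_b `degradation_fit` objects (e.g. control and photoaging).
#' @param ratio_bounds length-2 interval around 1 inside which the rates are
#'   considered indistinguishable.
#' @return list with `ratio`, `classification` (`"a"`, `"b"`,
#'   `"indistinguishable"` or `NA`), `photoaging_like` (fit label or `NA`) and
#'   `flags` (character).
#' @export
slope_ratio <- function(fit_a, fit_b, ratio_bounds = c(2 / 3, 3 / 2)) {
  stopifnot(inherits(fit_a, "degradation_fit"), inherits(fit_b, "degradation_fit"))
  if (fit_b$k == 0) stop("slope_ratio: denominator slope is zero")
  ratio <- fit_a$k / fit_b$k
  flags <- character(0)
  if (sign(fit_a$k) != sign(fit_b$k)) {
    flags <- c(flags, "sign_discordant")
    return(list(ratio = ratio, classification = NA_character_,
                photoaging_like = NA_character_, flags = flags))
  }
  both_neg <- fit_a$ci_k[2] < 0 && fit_b$ci_k[2] < 0
  if (!both_neg) flags <- c(flags, "slope_not_significantly_negative")
  departs <- ratio < ratio_bounds[1] || ratio > ratio_bounds[2]
  if (both_neg && departs) {
    steeper <- if (abs(fit_a$k) > abs(fit_b$k)) "a" else "b"
    list(ratio = ratio, classification = steeper, photoaging_like = steeper,
         flags = flags)
  } else {
    list(ratio = ratio, classification = "indistinguishable",
         photoaging_like = NA_character_, flags = flags)
  }
}

#' Week-by-week group comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per week between the two
#' groups, exact when the combined sample size is at most 20 and no ties are
#' present, otherwise the normal approximation with continuity and tie
#' correction. Weeks where either group has no observation are skipped with a
#' warning. No multiple-testing correction is applied across weeks.
#'
#' @param cohort cohort data.frame (see [simulate_cohort()] /
#'   [read_cohort_csv()]).
#' @param variable `"eta_collagen"` or `"eta_porphyrins"`.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame: `week`, per-group `mean`/`sd`/`n`, `p_value`,
#'   `significant`.
#' @export
weekly_group_comparison <- function(cohort,
                                    variable = c("eta_collagen", "eta_porphyrins"),
                                    alpha = 0.05) {
  variable <- match.arg(variable)
  obs <- cohort[cohort$status == "observed" & !is.na(cohort[[variable]]), ]
  groups <- sort(unique(obs$group))
  if (length(groups) != 2) stop("weekly_group_comparison: need exactly 2 groups")
  out <- lapply(sort(unique(obs$week)), function(w) {
    x <- obs[[variable]][obs$week == w & obs$group == groups[1]]
    y <- obs[[variable]][obs$week == w & obs$group == groups[2]]
    if (length(x) == 0 || length(y) == 0) {
      warning(sprintf("weekly_group_comparison: week %d skipped (empty group)", w))
      return(NULL)
    }
    p <- mann_whitney_p(x, y)
    data.frame(week = w,
               mean_1 = mean(x), sd_1 = stats::sd(x), n_1 = length(x),
               mean_2 = mean(y), sd_2 = stats::sd(y), n_2 = length(y),
               p_value = p, significant = is.finite(p) && p < alpha)
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- groups
  attr(res, "variable") <- variable
  res
}

# Two-sided Mann-Whitney p-value: exact for combined n <= 20 without ties,
# normal approximation (continuity + tie correction) otherwise.
mann_whitney_p <- function(x, y) {
  exact <- (length(x) + length(y)) <= 20
  has_ties <- anyDuplicated(c(x, y)) > 0
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact && !has_ties, correct = TRUE)$p.value)
}

#' Shapiro-Wilk normality check
#'
#' Annotates reports with a normality statistic; the group comparisons
#' themselves are rank-based regardless of the outcome.
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return list with `statistic` and `p_value`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("normality_check: sample size must be in [3, 5000]")
  if (stats::sd(values) == 0) stop("normality_check: sample is constant (zero variance)")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Group degradation report
#'
#' Fits the degradation line per group on pooled animal-week means, compares
#' the groups weekly, and applies the slope-ratio criterion
#' (control : photoaging).
#'
#' @param cohort cohort data.frame.
#' @param ratio_bounds passed to [slope_ratio()].
#' @return list with per-group `fits`, `weekly` comparison table, and
#'   `ratio` (control slope / photoaging slope plus classification).
#' @export
degradation_report <- function(cohort, ratio_bounds = c(2 / 3, 3 / 2)) {
  obs <- observed_rows(cohort)
  fits <- lapply(split(obs, obs$group), function(d)
    fit_linear_degradation(d$week, d$eta_collagen))
  weekly <- weekly_group_comparison(cohort, "eta_collagen")
  ratio <- if (all(c("control", "photoaging") %in% names(fits)))
    slope_ratio(fits$control, fits$photoaging, ratio_bounds) else NULL
  list(fits = fits, weekly = weekly, ratio = ratio)
}
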