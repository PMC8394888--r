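# Longitudinal cohort simulator: photoaging (chronic UVA) vs control
# (chronoaging) groups followed weekly for eta_collagen and eta_porphyrins,
# with scheduled biopsy withdrawals and anesthetic mortality.

# Weekly group means of eta_porphyrins used by the generator. Weeks 1-3 and
# 5-12 are the observed series; week 4 (absent from the observed series) is
# interpolated as the mean of weeks 3 and 5 and flagged here as synthetic.
porphyrin_week_means <- function() {
  list(
    control    = c(0.05, 0.06, 0.06, 0.05, 0.04, 0.05, 0.04, 0.04, 0.04, 0.04, 0.04, 0.05),
    photoaging = c(0.06, 0.06, 0.07, 0.055, 0.04, 0.04, 0.05, 0.05, 0.03, 0.05, 0.04, 0.04))
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the study conditions: 25 photoaging + 10 control
#' animals followed for 12 weeks; per-group generative lines for the mean
#' eta_collagen trajectory (control intercept 0.431, slope -0.003/week;
#' photoaging intercept 0.420, slope -0.006/week); five measurement sites per
#' animal-week with within-animal site SD 0.02 and a between-animal intercept
#' SD of 0.01; biopsy withdrawals of 3 photoaging + 1 control animal after
#' weeks 5, 10 and 12; and per-week mortality hazards calibrated so the
#' expected counts remaining at week 10 are 8 (photoaging) and 3 (control).
#'
#' @param n_photoaging,n_control group sizes.
#' @param weeks observation span in weeks.
#' @param gen_line named list of `c(b =, k =)` per group: mean trajectory
#'   `eta = b + k * t`, `t` in weeks (first measurement at t = 1).
#' @param noise_sd_between between-animal SD of the latent intercept.
#' @param noise_sd_within within-animal (site-to-site) SD.
#' @param n_sites measurement sites averaged per animal-week.
#' @param porphyrin_means named list of length-`weeks` weekly group means of
#'   eta_porphyrins.
#' @param porphyrin_sd site-to-site SD of eta_porphyrins.
#' @param withdrawal_weeks weeks after whose measurement animals are
#'   withdrawn for biopsy.
#' @param withdrawal_n named vector: animals withdrawn per group at each
#'   withdrawal week.
#' @param mortality_hazard named per-group (or scalar, recycled) per-week
#'   death probability, applied after each week's measurement.
#' @param seed integer seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_photoaging = 25, n_control = 10, weeks = 12,
                          gen_line = list(control    = c(b = 0.431, k = -0.003),
                                          photoaging = c(b = 0.420, k = -0.006)),
                          noise_sd_between = 0.01, noise_sd_within = 0.02,
                          n_sites = 5,
                          porphyrin_means = porphyrin_week_means(),
                          porphyrin_sd = 0.01,
                          withdrawal_weeks = c(5, 10, 12),
                          withdrawal_n = c(photoaging = 3, control = 1),
                          mortality_hazard = c(photoaging = 0.068, control = 0.080),
                          seed = 1L) {
  stopifnot(n_photoaging > 0, n_control > 0, weeks >= 1,
            noise_sd_between >= 0, noise_sd_within >= 0, n_sites >= 1,
            porphyrin_sd >= 0)
  for (g in c("control", "photoaging")) {
    b <- gen_line[[g]][["b"]]
    if (b <= 0 || b >= 1) stop("cohort_config: intercept b must lie in (0, 1)")
    if (length(porphyrin_means[[g]]) < weeks)
      stop("cohort_config: porphyrin_means shorter than the observation span")
  }
  if (length(mortality_hazard) == 1L)
    mortality_hazard <- c(photoaging = unname(mortality_hazard),
                          control = unname(mortality_hazard))
  if (any(mortality_hazard < 0 | mortality_hazard > 1))
    stop("cohort_config: mortality hazard must be a probability")
  structure(list(
    n_photoaging = n_photoaging, n_control = n_control, weeks = weeks,
    gen_line = gen_line, noise_sd_between = noise_sd_between,
    noise_sd_within = noise_sd_within, n_sites = n_sites,
    porphyrin_means = porphyrin_means, porphyrin_sd = porphyrin_sd,
    withdrawal_weeks = withdrawal_weeks, withdrawal_n = withdrawal_n,
    mortality_hazard = mortality_hazard, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Simulate a longitudinal cohort
#'
#' Each animal carries a latent line `b_i + k_g * t` (intercept jittered by
#' the between-animal SD). Each observed week produces `n_sites` site
#' measurements with within-animal noise, averaged to one value per
#' animal-week and clipped to \[0, 1\]. Porphyrin indices are drawn about the
#' configured weekly group means. After each week's measurement, scheduled
#' biopsy withdrawals remove animals (chosen at random among those on study),
#' and each remaining animal dies with the per-week mortality hazard. Records
#' after withdrawal or death are emitted with `NA` values and a status flag;
#' no imputation is performed.
#'
#' @param config a [cohort_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame with columns `animal_id`, `group`, `week`,
#'   `eta_collagen`, `eta_porphyrins`, `status`
#'   (`observed`/`withdrawn`/`dead`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  groups <- list(photoaging = config$n_photoaging, control = config$n_control)
  rows <- list()
  for (g in names(groups)) {
    n <- groups[[g]]
    ids <- sprintf("%s_%02d", substr(g, 1, 4), seq_len(n))
    line <- config$gen_line[[g]]
    b_i <- stats::rnorm(n, line[["b"]], config$noise_sd_between)
    status <- rep("observed", n)  # current fate per animal
    hazard <- config$mortality_hazard[[g]]
    for (t in seq_len(config$weeks)) {
      on_study <- status == "observed"
      eta_c <- eta_p <- rep(NA_real_, n)
      if (any(on_study)) {
        mu <- b_i[on_study] + line[["k"]] * t
        eta_c[on_study] <- vapply(mu, function(m) {
          clip01(mean(stats::rnorm(config$n_sites, m, config$noise_sd_within)))
        }, numeric(1))
        mu_p <- config$porphyrin_means[[g]][t]
        eta_p[on_study] <- vapply(which(on_study), function(i) {
          clip01(mean(stats::rnorm(config$n_sites, mu_p, config$porphyrin_sd)))
        }, numeric(1))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = ids, group = g, week = t,
        eta_collagen = eta_c, eta_porphyrins = eta_p, status = status)
      # post-measurement events: scheduled biopsy withdrawal, then mortality
      if (t %in% config$withdrawal_weeks) {
        k_w <- min(config$withdrawal_n[[g]], sum(status == "observed"))
        if (k_w > 0) {
          pick <- sample(which(status == "observed"), k_w)
          status[pick] <- "withdrawn"
        }
      }
      alive <- which(status == "observed")
      if (length(alive) > 0 && hazard > 0) {
        died <- alive[stats::runif(length(alive)) < hazard]
        status[died] <- "dead"
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$animal_id, out$week), ]
  rownames(out) <- NULL
  out
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Rows with a measured value
#'
#' Convenience filter for the observed (non-censored) records of a simulated
#' or loaded cohort table.
#'
#' @param cohort a cohort data.frame.
#' @return the subset with `status == "observed"`.
#' @export
observed_rows <- function(cohort) {
  cohort[cohort$status == "observed" & !is.na(cohort$eta_collagen), ]
}
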