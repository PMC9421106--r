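# Simulated SMART-style cluster surveys drawn from the true prevalence
# surface, with anthropometry consistent with the drawn case status.

#' Simulate one cluster survey of children 6-59 months
#'
#' Draws a multi-stage cluster sample from the world's true prevalence
#' surface at one stratum-month.  A shared normal cluster effect on the logit
#' scale induces the configured intra-cluster correlation; the cluster-level
#' intercept is adjusted by quadrature so the marginal prevalence equals the
#' truth exactly at any ICC.  Case status for the weight-for-height and MUAC
#' definitions is drawn per child (sharing the cluster effect, which also
#' correlates the two families); weight-for-height z-scores and MUAC values
#' are then drawn from normal distributions truncated to the region implied
#' by the drawn status, so that dichotomising at -3/-2 z (or 115/125 mm)
#' reproduces that status.  Weight is back-solved from the drawn z-score
#' through the world's LMS reference, so reanalysis recovers the z-scores.
#' Bilateral oedema is a rare independent Bernoulli that overrides
#' anthropometry towards SAM; the category draw is conditioned on oedema so
#' the marginal SAM/GAM probabilities still equal the truth.  A small
#' configured fraction of records get a missing weight or an out-of-range
#' age, to exercise downstream exclusion rules.
#'
#' @param world a [generate_world()] result.
#' @param stratum stratum id present in `world$strata`.
#' @param month calendar month present in `world$calendar`.
#' @param config optional override of `world$config`.
#' @return a list with `children` (one row per measured child) and `meta`
#'   (one-row survey metadata tibble with quality score, sampling coverage
#'   and the analysis weight).
#' @export
generate_survey <- function(world, stratum, month, config = world$config) {
  config <- validate_generator_config(unclass(config))
  if (!stratum %in% world$strata$stratum_id || !month %in% world$calendar$month) {
    abort(sprintf("unknown stratum-month: %s / %s", stratum, month),
          class = "nutcast_lookup_error")
  }
  s_idx <- match(stratum, world$strata$stratum_id)
  set.seed(derive_seed(config$seed, 1000L + s_idx * nrow(world$calendar) + month))

  truth <- world$truth_prevalence |>
    filter(.data$stratum_id == stratum, .data$month == .env$month)
  p_truth <- setNames(truth$p, truth$outcome)
  n_cl <- config$clusters_per_survey
  n_ch <- config$children_per_cluster
  n <- n_cl * n_ch

  sigma2 <- icc_to_sigma2(config$icc)
  u <- if (sigma2 > 0) rnorm(n_cl, 0, sqrt(sigma2)) else rep(0, n_cl)
  cluster_p <- function(p) {
    lp <- qlogis(p)
    delta <- if (sigma2 > 0) logit_marginal_adjust(lp, sigma2) else 0
    plogis(lp + delta + u)  # length n_cl
  }
  p_cl <- lapply(p_truth, cluster_p)
  # ensure SAM <= GAM cluster-wise (the marginal adjustment can, in
  # principle, let the curves cross at extreme cluster effects)
  p_cl$gam_wfh <- pmax(p_cl$gam_wfh, p_cl$sam_wfh)
  p_cl$gam_muac <- pmax(p_cl$gam_muac, p_cl$sam_muac)

  cluster_id <- rep(seq_len(n_cl), each = n_ch)
  oed <- runif(n) < config$oedema_rate
  cond <- function(p) pmin(1, pmax(0, (p - config$oedema_rate) / (1 - config$oedema_rate)))

  draw_cat <- function(p_sam_cl, p_gam_cl) {
    ps <- cond(p_sam_cl)[cluster_id]
    pg <- pmax(cond(p_gam_cl)[cluster_id], ps)
    v <- runif(n)
    ifelse(v < ps, "sam", ifelse(v < pg, "mam", "none"))
  }
  cat_wfh <- draw_cat(p_cl$sam_wfh, p_cl$gam_wfh)
  cat_muac <- draw_cat(p_cl$sam_muac, p_cl$gam_muac)

  # anthropometry consistent with the drawn status
  mu_whz <- -2 - qnorm(cond(mean(p_cl$gam_wfh)))      # base N(mu, 1)
  whz <- draw_truncated_by_cat(cat_wfh, mu_whz, 1, c(-3, -2))
  mu_muac <- 125 - 11 * qnorm(cond(mean(p_cl$gam_muac)))
  muac <- draw_truncated_by_cat(cat_muac, mu_muac, 11, c(115, 125))

  age <- sample(6:59, n, replace = TRUE)
  out_age <- runif(n) < config$age_out_rate
  age[out_age] <- sample(60:70, sum(out_age), replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  height <- pmin(119, pmax(46, 65 + 1.0 * (age - 6) - 0.004 * (age - 6)^2 +
                             rnorm(n, 0, 3)))
  par <- lms_interp(world$lms, sex, height)
  weight <- lms_value(whz, par[, "L"], par[, "M"], par[, "S"])
  weight[runif(n) < config$missing_measure_rate] <- NA_real_

  survey_id <- sprintf("%s_m%03d", stratum, month)
  children <- tibble(
    survey_id = survey_id,
    cluster_id = cluster_id,
    age_months = age,
    sex = sex,
    weight_kg = round(weight, 3),
    height_cm = round(height, 1),
    muac_mm = muac,
    oedema = oed,
    whz = NA_real_
  )
  # recompute the drawn z from the rounded measurements is deliberately NOT
  # done here: whz is left for survey_reanalysis::compute_whz() to fill.

  q_raw <- runif(1, 0, 0.25)
  coverage <- if (runif(1) < 0.7) 1 else runif(1, 0.7, 1)
  meta <- tibble(
    survey_id = survey_id,
    stratum_id = stratum,
    month = month,
    design = "cluster",
    quality_score_raw = q_raw,
    quality_rescaled = rescale_quality(q_raw),
    sampling_coverage = coverage,
    analysis_weight = rescale_quality(q_raw) * coverage
  )
  list(children = children, meta = meta)
}

# Draw each element from N(mu, sd) truncated to the interval implied by its
# category: sam < cuts[1], mam in [cuts[1], cuts[2]), none >= cuts[2].
draw_truncated_by_cat <- function(cat, mu, sd, cuts) {
  n <- length(cat)
  out <- numeric(n)
  i <- cat == "sam"
  out[i] <- rnorm_trunc(sum(i), mu, sd, upper = cuts[1] - 1e-9)
  i <- cat == "mam"
  out[i] <- rnorm_trunc(sum(i), mu, sd, lower = cuts[1], upper = cuts[2] - 1e-9)
  i <- cat == "none"
  out[i] <- rnorm_trunc(sum(i), mu, sd, lower = cuts[2])
  out
}

#' Simulate a survey schedule across the world
#'
#' Surveys a random fraction of eligible stratum-months (those with at least
#' `lag_horizon` months of predictor history, so lagged features exist) and
#' simulates each survey.  The schedule is deterministic given the seed.
#'
#' @param world a [generate_world()] result.
#' @param config optional override of `world$config`.
#' @param schedule optional explicit tibble (`stratum_id`, `month`) of
#'   stratum-months to survey, bypassing random scheduling.
#' @return a list with `children` (all surveys stacked) and `meta` (one row
#'   per survey).
#' @export
generate_surveys <- function(world, config = world$config, schedule = NULL) {
  config <- validate_generator_config(unclass(config))
  if (is.null(schedule)) {
    eligible <- tidyr::crossing(world$strata["stratum_id"],
                                filter(world$calendar, .data$month > config$lag_horizon))
    set.seed(derive_seed(config$seed, 5L))
    n_take <- max(1, round(config$survey_fraction * nrow(eligible)))
    schedule <- eligible[sort(sample.int(nrow(eligible), n_take)), ]
  }
  sims <- purrr::map2(schedule$stratum_id, schedule$month,
                      function(s, m) generate_survey(world, s, m, config))
  list(children = purrr::map_dfr(sims, "children"),
       meta = purrr::map_dfr(sims, "meta"))
}

#' Write a simulated world to plain-text CSV files
#'
#' Writes the four external interfaces of the generator: child records,
#' survey metadata, the long-format predictor panel and population
#' denominators, plus the LMS reference used.
#'
#' @param world a [generate_world()] result.
#' @param surveys a [generate_surveys()] result.
#' @param panel a [generate_predictor_panel()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_world_csvs <- function(world, surveys, panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("children.csv", "survey_meta.csv",
                            "predictor_panel.csv", "population.csv",
                            "lms_reference_synthetic.csv",
                            "truth_prevalence.csv"))
  readr::write_csv(surveys$children, paths[1])
  readr::write_csv(surveys$meta, paths[2])
  readr::write_csv(panel, paths[3])
  readr::write_csv(world$population, paths[4])
  readr::write_csv(world$lms, paths[5])
  readr::write_csv(world$truth_prevalence, paths[6])
  invisible(paths)
}
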