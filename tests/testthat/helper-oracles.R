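# Shared fixtures and independent brute-force oracles used across test files.
suppressMessages({
  library(dplyr)
  library(tibble)
})

# ---- fixture generators -----------------------------------------------------

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_strata = 5, n_months = 18, clusters_per_survey = 8,
         children_per_cluster = 12, seed = seed),
    list(...))
  do.call(generator_config, args)
}

# random child records with known fields (no generator involvement)
random_children <- function(n, seed) {
  set.seed(seed)
  tibble(
    survey_id = sample(paste0("sv", 1:3), n, replace = TRUE),
    cluster_id = sample(1:5, n, replace = TRUE),
    age_months = sample(c(2:70, NA), n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    weight_kg = runif(n, 3, 20),
    height_cm = runif(n, 50, 110),
    muac_mm = ifelse(runif(n) < 0.1, NA, runif(n, 90, 180)),
    oedema = runif(n) < 0.02,
    whz = ifelse(runif(n) < 0.12, NA, rnorm(n, -0.8, 2.2))
  )
}

# random matched prediction/observation pair sets for the evaluation oracles
random_pair_set <- function(n, seed) {
  set.seed(seed)
  obs <- pmax(0, rnorm(n, 0.12, 0.08))
  pred <- pmax(0, obs + rnorm(n, 0.01, 0.05))
  half_o <- runif(n, 0.005, 0.05)
  half_p <- runif(n, 0.005, 0.05)
  tibble(
    stratum_id = paste0("S", seq_len(n)), month = seq_len(n),
    pred_point = pred,
    pred_ci_low_95 = pred - half_p, pred_ci_high_95 = pred + half_p,
    obs_point = obs,
    obs_ci_low_95 = pmax(0, obs - half_o), obs_ci_high_95 = obs + half_o,
    obs_ci_low_80 = pmax(0, obs - 0.7 * half_o), obs_ci_high_80 = obs + 0.7 * half_o
  )
}

# stratum-month aggregated table for the random-forest track
rf_table_fixture <- function(n = 120, seed = 1, signal = TRUE, k = 4) {
  set.seed(seed)
  grid <- tidyr::crossing(stratum_id = sprintf("S%02d", 1:10), month = 1:24)
  sm <- grid[sample(nrow(grid), n), ]
  X <- matrix(runif(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
  y <- if (signal) 0.1 + 0.2 * X[, 1] + rnorm(n, 0, 0.02) else rnorm(n, 0.2, 0.05)
  tab <- dplyr::bind_cols(
    tibble(survey_id = paste0("sv", 1:n), stratum_id = sm$stratum_id,
           month = sm$month, y = y, w = runif(n, 0.5, 1)),
    tibble::as_tibble(X))
  attr(tab, "outcome") <- "gam_wfh"
  tab
}

# ---- brute-force oracles ----------------------------------------------------

bf_mse <- function(pairs) {
  s <- 0
  for (i in seq_len(nrow(pairs))) s <- s + (pairs$pred_point[i] - pairs$obs_point[i])^2
  s / nrow(pairs)
}

bf_relative_bias <- function(pairs) {
  s <- 0; k <- 0
  for (i in seq_len(nrow(pairs))) {
    if (pairs$obs_point[i] != 0) {
      s <- s + (pairs$pred_point[i] - pairs$obs_point[i]) / pairs$obs_point[i]
      k <- k + 1
    }
  }
  if (k == 0) NA_real_ else s / k
}

bf_relative_precision <- function(pred) {
  s <- 0; k <- 0
  for (i in seq_len(nrow(pred))) {
    if (pred$point[i] != 0) {
      s <- s + ((pred$ci_high_95[i] - pred$ci_low_95[i]) / 2) / pred$point[i]
      k <- k + 1
    }
  }
  if (k == 0) NA_real_ else s / k
}

bf_coverage <- function(pairs, suffix) {
  hits <- 0; k <- 0
  lo <- pairs[[paste0("obs_ci_low_", suffix)]]
  hi <- pairs[[paste0("obs_ci_high_", suffix)]]
  for (i in seq_len(nrow(pairs))) {
    if (!is.na(lo[i]) && !is.na(hi[i])) {
      k <- k + 1
      if (pairs$pred_point[i] >= lo[i] && pairs$pred_point[i] <= hi[i]) hits <- hits + 1
    }
  }
  if (k == 0) NA_real_ else hits / k
}

bf_sens_spec <- function(pairs, tau) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(pairs))) {
    op <- pairs$obs_point[i] >= tau
    pp <- pairs$pred_point[i] >= tau
    if (op && pp) tp <- tp + 1
    if (op && !pp) fn <- fn + 1
    if (!op && pp) fp <- fp + 1
    if (!op && !pp) tn <- tn + 1
  }
  list(sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_, n_pos = tp + fn,
       spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_, n_neg = tn + fp)
}

# independent three-rule exclusion filter (per-rule, then first-match order)
bf_exclusions <- function(children, flag_limit = 5, age_range = c(6, 59),
                          center = "survey_mean") {
  oed <- !is.na(children$oedema) & children$oedema
  r_missing <- is.na(children$age_months) |
    (is.na(children$whz) & is.na(children$muac_mm) & !oed)
  r_age <- children$age_months < age_range[1] | children$age_months > age_range[2]
  r_age[is.na(r_age)] <- FALSE
  r_age <- r_age & !r_missing
  ctr <- rep(0, nrow(children))
  if (center == "survey_mean") {
    for (s in unique(children$survey_id)) {
      idx <- children$survey_id == s
      elig <- idx & !r_missing & !r_age & !is.na(children$whz)
      ctr[idx] <- mean(children$whz[elig])
    }
  }
  r_flag <- !is.na(children$whz) & abs(children$whz - ctr) > flag_limit & !oed
  r_flag[is.na(r_flag)] <- FALSE
  reason <- rep("none", nrow(children))
  for (i in seq_len(nrow(children))) {
    if (r_missing[i]) reason[i] <- "missing"
    else if (r_age[i]) reason[i] <- "age_out_of_range"
    else if (r_flag[i]) reason[i] <- "flagged_outlier"
  }
  reason
}
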