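# Synthetic world generation: strata, populations, autocorrelated predictor
# series and a logistic-link true prevalence surface with known coefficients.

LIVELIHOODS <- c("agriculturalist", "agropastoral", "pastoralist", "displaced", "urban")
BINARY_OUTCOMES <- c("sam_wfh", "gam_wfh", "sam_muac", "gam_muac")

# Stationary AR(1) series of length n with lag-1 correlation rho and marginal
# standard deviation sd around 0.
ar1_series <- function(n, rho, sd = 1) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  }
  x
}

#' Generate a synthetic multi-stratum world with known ground truth
#'
#' Builds the full data-generating state for one simulated setting: strata
#' with static livelihood labels, monthly population denominators, complete
#' autocorrelated predictor series (including a pre-calendar burn-in so that
#' lagged features exist from the first calendar month), and the true
#' stratum-month prevalence surface for the four binary case definitions.
#' Truth is an inverse-logit linear predictor on the standardised 1-3-month
#' lagged means of the configured predictor variables plus a livelihood
#' offset; the realised coefficients and design are stored on the world so
#' downstream estimates can be compared against them.
#'
#' @param config a [generator_config()] object.
#' @return an object of class `nutcast_world`: a list with elements
#'   `config`, `strata`, `calendar`, `population`, `series` (complete
#'   long-format predictor values, calendar months only), `series_full`
#'   (including burn-in months, used internally for lags), `variable_meta`,
#'   `scaling`, `truth_design` and `truth_prevalence`.
#' @export
generate_world <- function(config) {
  config <- validate_generator_config(unclass(config))
  set.seed(derive_seed(config$seed, 1L))

  strata <- tibble(
    stratum_id = sprintf("S%02d", seq_len(config$n_strata)),
    livelihood = sample(LIVELIHOODS, config$n_strata, replace = TRUE)
  )
  calendar <- tibble(month = seq_len(config$n_months))
  months_full <- seq(1 - config$lag_horizon, config$n_months)

  # population: stratum base size around 100k with mild deterministic growth
  base_pop <- round(exp(rnorm(config$n_strata, log(1e5), 0.5)))
  population <- tidyr::crossing(strata["stratum_id"], calendar) |>
    mutate(population = pmax(1, round(
      base_pop[match(.data$stratum_id, strata$stratum_id)] *
        (1.002)^(.data$month - 1))))

  series_full <- purrr::map_dfr(seq_len(config$n_strata), function(i) {
    set.seed(derive_seed(config$seed, 100L + i))
    n <- length(months_full)
    rho <- config$predictor_ar
    pop_i <- base_pop[i]
    seas <- sin(2 * pi * months_full / 12)
    tibble(
      stratum_id = strata$stratum_id[i],
      month = rep(months_full, times = 8),
      variable = rep(c("rainfall_mm", "mean_ndvi", "conflict_deaths",
                       "measles_cases", "water_price", "tot_goat_cereal",
                       "humanitarian_presence", "idp_prop"), each = n),
      value = c(
        pmax(0, 80 + 40 * seas + ar1_series(n, rho, 25)),
        pmin(0.9, pmax(0.02, 0.30 + 0.10 * sin(2 * pi * (months_full + 2) / 12) +
                         ar1_series(n, rho, 0.05))),
        rpois(n, exp(log(pop_i / 1e5 * 3) + ar1_series(n, rho, 0.6))),
        rpois(n, exp(log(pop_i / 1e5 * 8) + ar1_series(n, rho, 0.7))),
        exp(log(15000) + ar1_series(n, rho, 0.20)),
        exp(log(30000) + ar1_series(n, rho, 0.15)),
        pmax(0, round(20 + ar1_series(n, 0.9, 3))),
        plogis(qlogis(0.08) + ar1_series(n, 0.9, 0.3))
      )
    )
  })

  variable_meta <- tibble(
    variable = c("rainfall_mm", "mean_ndvi", "conflict_deaths", "measles_cases",
                 "water_price", "tot_goat_cereal", "humanitarian_presence",
                 "idp_prop"),
    type = c("climate", "climate", "count", "count", "price", "price",
             "other", "other")
  )

  # derived rate variables per 100,000 used by the truth surface
  pop_full <- tidyr::crossing(strata["stratum_id"], tibble(month = months_full)) |>
    mutate(population = pmax(1, round(
      base_pop[match(.data$stratum_id, strata$stratum_id)] *
        (1.002)^(.data$month - 1))))
  rates <- series_full |>
    filter(.data$variable %in% c("conflict_deaths", "measles_cases")) |>
    left_join(pop_full, by = c("stratum_id", "month")) |>
    mutate(variable = ifelse(.data$variable == "conflict_deaths",
                             "conflict_deaths_rate", "measles_rate"),
           value = .data$value / .data$population * 1e5) |>
    select("stratum_id", "month", "variable", "value")
  truth_source <- bind_rows(series_full, rates)

  # 1-3-month lagged means of the effect variables, for calendar months
  eff_vars <- names(config$effect_sizes)
  lagged <- purrr::map_dfr(eff_vars, function(v) {
    sv <- truth_source |> filter(.data$variable == v) |> arrange(.data$stratum_id, .data$month)
    sv |>
      group_by(.data$stratum_id) |>
      mutate(lagmean = (dplyr::lag(.data$value, 1) + dplyr::lag(.data$value, 2) +
                          dplyr::lag(.data$value, 3)) / 3) |>
      ungroup() |>
      filter(.data$month >= 1) |>
      transmute(.data$stratum_id, .data$month, variable = v, value = .data$lagmean)
  })
  scaling <- lagged |>
    group_by(.data$variable) |>
    summarise(center = mean(.data$value), scale = sd(.data$value), .groups = "drop") |>
    mutate(scale = ifelse(.data$scale < 1e-12, 1, .data$scale))
  truth_design <- lagged |>
    left_join(scaling, by = "variable") |>
    mutate(value = (.data$value - .data$center) / .data$scale) |>
    select("stratum_id", "month", "variable", "value") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    left_join(strata, by = "stratum_id") |>
    arrange(.data$stratum_id, .data$month)

  lp_common <- as.matrix(truth_design[, eff_vars, drop = FALSE]) %*%
    config$effect_sizes[eff_vars] +
    config$livelihood_effects[truth_design$livelihood]
  truth_prevalence <- purrr::map_dfr(BINARY_OUTCOMES, function(o) {
    tibble(stratum_id = truth_design$stratum_id,
           month = truth_design$month,
           outcome = o,
           p = plogis(config$intercepts[[o]] + as.numeric(lp_common)))
  })
  stopifnot(all(truth_prevalence$p > 0 & truth_prevalence$p < 1))

  structure(list(
    config = structure(config, class = "nutcast_config"),
    seed = config$seed,
    strata = strata,
    calendar = calendar,
    population = population,
    series = filter(series_full, .data$month >= 1),
    series_full = series_full,
    variable_meta = variable_meta,
    scaling = scaling,
    truth_design = truth_design,
    truth_prevalence = truth_prevalence,
    lms = synthetic_lms_table()
  ), class = "nutcast_world")
}

#' @export
print.nutcast_world <- function(x, ...) {
  cat(sprintf("<nutcast_world> %d strata x %d months (seed %d)\n",
              nrow(x$strata), nrow(x$calendar), x$seed))
  cat("  true prevalence ranges:\n")
  rng <- x$truth_prevalence |>
    group_by(.data$outcome) |>
    summarise(lo = min(.data$p), hi = max(.data$p), .groups = "drop")
  for (i in seq_len(nrow(rng))) {
    cat(sprintf("    %-9s %.3f - %.3f\n", rng$outcome[i], rng$lo[i], rng$hi[i]))
  }
  invisible(x)
}

#' Deliver the observable predictor panel, with block missingness
#'
#' Returns the long-format stratum-month predictor panel a modeller would
#' actually receive: the world's complete calendar-month series with
#' contiguous blocks of cells (2-4 consecutive months per block) removed at
#' the configured rate.  Cells removed are recorded with `value = NA` and
#' `is_missing = TRUE`; nothing is silently dropped.
#'
#' @param world a [generate_world()] result.
#' @param config optional override of `world$config`.
#' @return a tibble (`stratum_id`, `month`, `variable`, `value`,
#'   `is_missing`) with attribute `variable_meta`.
#' @export
generate_predictor_panel <- function(world, config = world$config) {
  config <- validate_generator_config(unclass(config))
  panel <- world$series |> mutate(is_missing = FALSE)
  rate <- config$missingness_block_rate
  if (rate > 0) {
    set.seed(derive_seed(config$seed, 7L))
    n_m <- nrow(world$calendar)
    panel <- panel |>
      group_by(.data$stratum_id, .data$variable) |>
      group_modify(function(df, key) {
        df <- arrange(df, .data$month)
        miss <- rep(FALSE, nrow(df))
        target <- rate * nrow(df)
        guard <- 0
        while (sum(miss) < target && guard < 10 * n_m) {
          start <- sample.int(nrow(df), 1)
          len <- sample(2:4, 1)
          for (t in start:min(nrow(df), start + len - 1)) {
            if (sum(miss) >= target) break
            miss[t] <- TRUE
          }
          guard <- guard + 1
        }
        df$is_missing <- miss
        df$value[miss] <- NA_real_
        df
      }) |>
      ungroup() |>
      select("stratum_id", "month", "variable", "value", "is_missing")
  }
  attr(panel, "variable_meta") <- world$variable_meta
  panel
}
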