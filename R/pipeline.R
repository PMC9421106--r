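# End-to-end orchestration: simulate -> reanalyse -> complete panel ->
# features -> GLM and RF tracks -> evaluation reports.

#' Complete a raw predictor panel
#'
#' Applies the completion chain to a long-format panel with missingness:
#' price-type variables are imputed from the other strata's markets (0.7 x
#' nearest market + 0.3 x mean of the rest, nearest defined by stratum
#' order), slowly varying service variables are linearly interpolated,
#' count variables are converted to per-100,000 rates using the population
#' denominators, and any remaining missing cells are filled by
#' chained-equations imputation.  Smoothed (spline) versions of price
#' variables and trailing 3-month rolling means of every time-varying
#' variable are added as derived columns (originals retained).
#'
#' @param panel long panel from [generate_predictor_panel()] (or the same
#'   schema read from CSV), with a `variable_meta` attribute or a
#'   `variable_meta` argument classifying variables as `count`, `price`,
#'   `climate` or `other`.
#' @param population tibble (`stratum_id`, `month`, `population`).
#' @param variable_meta optional tibble (`variable`, `type`).
#' @param seed seed for the chained imputation.
#' @param missingness_threshold screening threshold (default 0.30).
#' @return a list with `long` (completed long panel including derived
#'   variables), `wide` (stratum-month wide table), and `screen` (the
#'   missingness screening detail).
#' @export
complete_panel <- function(panel, population, variable_meta = NULL,
                           seed = 1L, missingness_threshold = 0.30) {
  panel <- as_tibble(panel)
  variable_meta <- variable_meta %||% attr(panel, "variable_meta")
  if (is.null(variable_meta)) {
    variable_meta <- tibble(variable = unique(panel$variable), type = "other")
  }
  screen <- screen_missingness(panel, missingness_threshold)
  panel <- filter(panel, .data$variable %in% screen$kept)
  strata <- sort(unique(panel$stratum_id))
  months <- sort(unique(panel$month))
  vtype <- setNames(variable_meta$type, variable_meta$variable)

  get_wide_var <- function(v) {
    panel |>
      filter(.data$variable == v) |>
      select("stratum_id", "month", "value") |>
      tidyr::pivot_wider(names_from = "stratum_id", values_from = "value") |>
      arrange(.data$month)
  }
  completed <- list()
  for (v in screen$kept) {
    wv <- get_wide_var(v)
    mat <- as.matrix(wv[, strata, drop = FALSE])
    type <- vtype[[v]] %||% "other"
    if (type == "price") {
      for (j in seq_along(strata)) {
        nearest_j <- if (length(strata) > 1) ifelse(j == 1, 2, j - 1) else j
        res <- impute_market(mat[, j], mat[, nearest_j],
                             mat[, -c(j), drop = FALSE])
        mat[, j] <- res$value
      }
    } else if (type == "other") {
      for (j in seq_along(strata)) {
        if (sum(!is.na(mat[, j])) >= 2) {
          mat[, j] <- interpolate_series(mat[, j], wv$month)$value
        }
      }
    }
    completed[[v]] <- tibble(month = rep(wv$month, length(strata)),
                             stratum_id = rep(strata, each = nrow(wv)),
                             variable = v, value = as.numeric(mat))
  }
  long <- bind_rows(completed)

  # count variables become per-population rates
  counts <- names(vtype)[vtype == "count" & names(vtype) %in% screen$kept]
  if (length(counts) > 0) {
    rate_name <- function(v) {
      known <- c(conflict_deaths = "conflict_deaths_rate",
                 measles_cases = "measles_rate")
      ifelse(v %in% names(known), known[v], paste0(v, "_rate"))
    }
    rates <- long |>
      filter(.data$variable %in% counts) |>
      left_join(as_tibble(population), by = c("stratum_id", "month")) |>
      mutate(variable = rate_name(.data$variable),
             value = per_capita_rate(.data$value, .data$population)) |>
      select("stratum_id", "month", "variable", "value")
    long <- bind_rows(long, rates)
  }

  wide <- long |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    arrange(.data$stratum_id, .data$month)
  wide <- impute_chained(wide, seed = seed)
  long <- wide |>
    tidyr::pivot_longer(-c("stratum_id", "month"), names_to = "variable",
                        values_to = "value")

  # derived columns: smoothed prices, trailing rolling means
  prices <- names(vtype)[vtype == "price" & names(vtype) %in% screen$kept]
  derived <- list()
  for (v in prices) {
    sm <- long |>
      filter(.data$variable == v) |>
      group_by(.data$stratum_id) |>
      arrange(.data$month, .by_group = TRUE) |>
      mutate(value = smooth_series(.data$value, .data$month),
             variable = paste0(v, "_smooth")) |>
      ungroup()
    derived[[length(derived) + 1]] <- sm
  }
  for (v in setdiff(unique(long$variable), prices)) {
    rm3 <- long |>
      filter(.data$variable == v) |>
      group_by(.data$stratum_id) |>
      arrange(.data$month, .by_group = TRUE) |>
      mutate(value = rolling_mean(.data$value),
             variable = paste0(v, "_roll3")) |>
      ungroup()
    derived[[length(derived) + 1]] <- rm3
  }
  long <- bind_rows(long, derived)
  list(long = long, wide = wide, screen = screen)
}

default_candidate_lags <- function(variable, climate = FALSE) {
  if (climate) {
    list(c(1, 3), c(4, 6), c(1, 6))
  } else {
    list(c(1, 3), c(2, 4), c(4, 6))
  }
}

# Weighted quantile (type-4-style interpolation on the weighted ECDF).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], numeric(1))
}

default_breakpoints <- function(x, w = rep(1, length(x))) {
  ok <- !is.na(x)
  br <- unique(weighted_quantile(x[ok], w[ok], c(0.25, 0.5, 0.75)))
  br[br > min(x[ok]) & br < max(x[ok])]
}

#' Run the full now-casting pipeline on a synthetic world
#'
#' Orchestrates every stage with one configuration and one seed: world
#' generation, survey simulation, survey reanalysis, predictor-panel
#' completion, lag-feature construction, the chronological 70/30 split,
#' per-predictor form and lag selection, all-subsets enumeration with
#' best-10% holdout shortlisting, LOOCV of the best candidate, the
#' random-forest track with jackknife intervals, and the evaluation report
#' for each requested outcome.  Deterministic given `seed`.
#'
#' @param config a [generator_config()]; its seed is replaced by `seed`.
#' @param seed master seed for the run.
#' @param outcomes outcome labels to model (default the two
#'   weight-for-height prevalences).
#' @param model_variables panel variables offered to the models (defaults
#'   to the generator's effect variables).
#' @param max_terms all-subsets size cap (default: number of selected
#'   specs).
#' @param n_draws interval-simulation draws per prediction (default 4000).
#' @param forecast_offset uniform extra lag in months (0 = now-cast,
#'   3 = three-month forecast).
#' @param rf_trees trees in the random forest (default 1000).
#' @return a `nutcast_run`: list with `world`, `surveys`, `reanalysis`,
#'   `features`, and per-outcome `glm` / `rf` result lists each containing
#'   the fitted objects, predictions and `report`.
#' @export
run_all <- function(config = generator_config(), seed = 1L,
                    outcomes = c("sam_wfh", "gam_wfh"),
                    model_variables = NULL, max_terms = NULL,
                    n_draws = 4000, forecast_offset = 0, rf_trees = 1000) {
  config <- validate_generator_config(
    utils::modifyList(unclass(config), list(seed = as.integer(seed))))
  world <- generate_world(config)
  surveys <- generate_surveys(world, config)
  panel <- generate_predictor_panel(world, config)
  reanalysis <- reanalyse_surveys(surveys$children, surveys$meta, world$lms)
  children <- apply_exclusions(compute_whz(surveys$children, world$lms))

  completed <- complete_panel(panel, world$population,
                              world$variable_meta, seed = derive_seed(seed, 21L))
  model_variables <- model_variables %||% names(config$effect_sizes)
  climate_vars <- world$variable_meta$variable[world$variable_meta$type == "climate"]

  # candidate lag specs per variable
  lag_specs <- list()
  for (v in model_variables) {
    for (lw in default_candidate_lags(v, climate = v %in% climate_vars)) {
      lag_specs[[length(lag_specs) + 1]] <- lag_spec(v, lw[1], lw[2])
    }
  }
  features <- build_features(completed$long, lag_specs,
                             reference = tidyr::crossing(world$strata["stratum_id"],
                                                         world$calendar),
                             forecast_offset = forecast_offset,
                             static = world$strata)
  split <- chronological_split(surveys$meta)

  run_outcome <- function(outcome) {
    frame <- build_model_frame(children, surveys$meta, features, outcome)
    f_train <- frame[frame$survey_id %in% split$train$survey_id, ]
    f_hold <- frame[frame$survey_id %in% split$holdout$survey_id, ]
    attr(f_train, "outcome") <- outcome
    attr(f_hold, "outcome") <- outcome

    # form + lag selection per variable
    specs <- purrr::map(model_variables, function(v) {
      lags <- default_candidate_lags(v, climate = v %in% climate_vars)
      cands <- list()
      for (lw in lags) {
        col <- lag_feature_name(lag_spec(v, lw[1], lw[2]))
        br <- default_breakpoints(f_train[[col]], f_train$w)
        cands[[length(cands) + 1]] <- list(column = col, form = "continuous",
                                           lag_start = lw[1])
        if (length(br) > 0) {
          cands[[length(cands) + 1]] <- list(column = col, form = "categorical",
                                             breaks = br, lag_start = lw[1])
        }
      }
      select_predictor_form(f_train, cands)
    })
    # static livelihood enters as a categorical spec when it varies
    if (dplyr::n_distinct(world$strata$livelihood) > 1) {
      specs <- c(specs, list(structure(
        list(column = "livelihood", form = "categorical",
             levels = sort(unique(world$strata$livelihood)), lag_start = 0),
        class = "nutcast_predictor_spec")))
    }

    candidates <- enumerate_models(specs, max_terms %||% length(specs))
    hold_keys <- distinct(f_hold, .data$stratum_id, .data$month)
    fitted <- purrr::imap(candidates, function(sp, i) {
      m <- tryCatch(fit_glm(f_train, sp), error = function(e) NULL)
      if (is.null(m) || !m$converged) return(NULL)
      hp <- predict_stratum_month(
        m, dplyr::semi_join(features, hold_keys, by = c("stratum_id", "month")),
        n_draws = n_draws, seed = derive_seed(seed, 300L + i),
        source = "holdout")
      list(model = m, holdout_pred = hp)
    })
    fitted <- purrr::compact(fitted)
    observed <- filter(reanalysis, .data$outcome == .env$outcome)
    obs_hold <- dplyr::semi_join(observed, split$holdout, by = "survey_id")
    short <- shortlist_models(fitted, obs_hold)
    best <- short[[1]]

    train_keys <- distinct(f_train, .data$stratum_id, .data$month)
    pred_train <- predict_stratum_month(
      best$model, dplyr::semi_join(features, train_keys, by = c("stratum_id", "month")),
      n_draws = n_draws, seed = derive_seed(seed, 401L), source = "train")
    pred_loocv <- loocv(f_train, best$model$specs, features,
                        n_draws = n_draws, seed = derive_seed(seed, 402L))
    glm_preds <- bind_rows(pred_train, pred_loocv[names(pred_train)],
                           best$holdout_pred)
    thr <- if (startsWith(outcome, "sam")) threshold_set("sam") else
      if (startsWith(outcome, "gam")) threshold_set("gam") else NULL
    glm_report <- build_report(glm_preds, observed, thr)

    # random-forest track on the same split and features
    rea_train <- dplyr::semi_join(reanalysis, split$train, by = "survey_id")
    rf_table <- aggregate_training_table(
      filter(rea_train, .data$outcome == .env$outcome), features, outcome)
    rf_fit <- fit_rf(rf_table, rf_config(n_trees = rf_trees,
                                         seed = derive_seed(seed, 500L)))
    rf_preds <- bind_rows(
      rf_predict_ci(rf_fit, dplyr::semi_join(features, train_keys,
                                             by = c("stratum_id", "month")),
                    source = "train", prevalence = !is.null(thr)),
      rf_predict_ci(rf_fit, dplyr::semi_join(features, hold_keys,
                                             by = c("stratum_id", "month")),
                    source = "holdout", prevalence = !is.null(thr)))
    rf_report <- build_report(select(rf_preds, -"se"), observed, thr)

    list(glm = list(specs = specs, n_candidates = length(fitted),
                    shortlist = short, best = best,
                    predictions = glm_preds, report = glm_report),
         rf = list(model = rf_fit, predictions = rf_preds, report = rf_report))
  }

  results <- purrr::map(setNames(outcomes, outcomes), run_outcome)
  structure(list(config = config, seed = seed, world = world,
                 surveys = surveys, reanalysis = reanalysis,
                 features = features, split = split, completed = completed,
                 results = results),
            class = "nutcast_run")
}

#' Write every report of a pipeline run
#'
#' Serialises the GLM and RF metrics reports of each outcome under
#' `dir/glm/` and `dir/rf/`.
#'
#' @param run a [run_all()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_run_reports <- function(run, dir) {
  paths <- character()
  for (outcome in names(run$results)) {
    paths <- c(paths,
               write_metrics_report(run$results[[outcome]]$glm$report,
                                    file.path(dir, "glm")),
               write_metrics_report(run$results[[outcome]]$rf$report,
                                    file.path(dir, "rf")))
  }
  invisible(paths)
}
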