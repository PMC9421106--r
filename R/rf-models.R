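# Random-forest regression on stratum-month aggregated outcomes, with
# infinitesimal-jackknife prediction intervals and permutation importance.

#' Random-forest configuration
#'
#' @param n_trees number of trees (default 1000).
#' @param mtry variables tried per split; default `ceiling(p / 3)`, the
#'   regression convention.
#' @param min_node_size minimum terminal node size (default 5).
#' @param seed integer seed.
#' @return a `nutcast_rf_config` object.
#' @export
rf_config <- function(n_trees = 1000, mtry = NULL, min_node_size = 5, seed = 1L) {
  if (n_trees < 1) abort("n_trees must be >= 1", class = "nutcast_config_error")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "nutcast_rf_config")
}

#' Aggregate reanalysed surveys into the RF training table
#'
#' One row per surveyed stratum-month: the survey's design-based point
#' estimate as the response, the stratum-month features, and the survey
#' analysis weight carried as a case weight.  Surveys whose features are
#' incomplete are dropped and reported.
#'
#' @param reanalysis a [reanalyse_surveys()] result.
#' @param features wide feature table keyed by (`stratum_id`, `month`).
#' @param outcome outcome label to extract.
#' @return tibble with `survey_id`, `stratum_id`, `month`, `y`, `w` and
#'   feature columns; dropped surveys in the `dropped` attribute.
#' @export
aggregate_training_table <- function(reanalysis, features, outcome) {
  rows <- reanalysis |>
    filter(.data$outcome == .env$outcome) |>
    transmute(.data$survey_id, .data$stratum_id, .data$month,
              y = .data$point, w = .data$analysis_weight) |>
    left_join(as_tibble(features), by = c("stratum_id", "month"))
  featcols <- setdiff(names(rows), c("survey_id", "stratum_id", "month", "y", "w"))
  ok <- complete.cases(rows[, featcols, drop = FALSE])
  out <- rows[ok, ]
  attr(out, "dropped") <- rows$survey_id[!ok]
  attr(out, "outcome") <- outcome
  out
}

#' Fit a random-forest regression on the aggregated table
#'
#' Grows a regression forest (default 1000 trees) on the stratum-month
#' table, with survey analysis weights as sampling weights in the bootstrap
#' draws, permutation variable importance, and inbag counts retained for
#' the jackknife interval estimator.  Deterministic given the seed.
#'
#' @param table an [aggregate_training_table()] result.
#' @param config an [rf_config()].
#' @return a `nutcast_rf` object: `forest` (ranger), `feature_names`,
#'   `importance`, `oob_mse`, `oob_r2`, `outcome`.
#' @export
fit_rf <- function(table, config = rf_config()) {
  featcols <- setdiff(names(table), c("survey_id", "stratum_id", "month", "y", "w"))
  if (nrow(table) < 1) abort("empty training table")
  if (nrow(table) < 10) warn("fewer than 10 rows: forest will be degenerate")
  d <- as.data.frame(table[, c("y", featcols)])
  degenerate <- nrow(d) < 2 || isTRUE(sd(d$y) < 1e-12)
  if (degenerate) warn("constant response: degenerate forest, importances are 0")
  mtry <- config$mtry %||% ceiling(length(featcols) / 3)
  forest <- ranger::ranger(
    y ~ ., data = d, num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_node_size, seed = config$seed,
    num.threads = 1, keep.inbag = TRUE, importance = "permutation",
    case.weights = table$w)
  imp <- forest$variable.importance
  if (degenerate) imp[] <- 0
  structure(list(forest = forest, feature_names = featcols,
                 importance = sort(imp, decreasing = TRUE),
                 oob_mse = forest$prediction.error,
                 oob_r2 = forest$r.squared,
                 outcome = attr(table, "outcome")),
            class = "nutcast_rf")
}

#' @export
print.nutcast_rf <- function(x, ...) {
  cat(sprintf("<nutcast_rf> outcome %s, %d trees, OOB MSE %.5f\n",
              x$outcome %||% "?", x$forest$num.trees, x$oob_mse))
  cat("top importance:\n")
  print(round(head(x$importance, 5), 5))
  invisible(x)
}

#' Random-forest predictions with jackknife intervals
#'
#' Ensemble-mean point predictions with standard errors from the
#' jackknife-after-bootstrap estimator over the bootstrap inclusion counts,
#' including the standard Monte-Carlo bias correction (`se.method = "jack"`;
#' the infinitesimal-jackknife variant is available via `se_method`); 95%
#' and 80% intervals are normal-theory `point +/- z * SE`.  Prevalence-scale
#' predictions are truncated to `[0, 1]`.  Negative bias-corrected variances
#' are floored at zero with a warning.
#'
#' @param model a [fit_rf()] result.
#' @param features target rows carrying the model's feature columns (plus
#'   `stratum_id`, `month`).
#' @param source label for the `source` column (default `"holdout"`).
#' @param prevalence logical: truncate predictions and intervals to
#'   `[0, 1]` (default `TRUE` for binary-outcome prevalences).
#' @param se_method `"jack"` (default) or `"infjack"`.
#' @return a tibble of prediction records in the same schema as
#'   [predict_stratum_month()], plus `se`.
#' @export
rf_predict_ci <- function(model, features, source = "holdout",
                          prevalence = TRUE, se_method = c("jack", "infjack")) {
  se_method <- match.arg(se_method)
  features <- as_tibble(features)
  fc <- model$feature_names
  ok <- complete.cases(features[, fc, drop = FALSE])
  feat <- features[ok, ]
  newdata <- as.data.frame(feat[, fc, drop = FALSE])
  pr <- tryCatch(
    suppressWarnings(
      predict(model$forest, data = newdata, type = "se", se.method = se_method,
              num.threads = 1)),
    error = function(e) {
      warn(paste("jackknife variance unavailable, floored at 0:",
                 conditionMessage(e)))
      p <- predict(model$forest, data = newdata, num.threads = 1)
      list(predictions = p$predictions, se = rep(0, nrow(newdata)))
    })
  se <- pr$se
  if (any(!is.finite(se))) {
    warn("non-finite jackknife variance floored at 0")
    se[!is.finite(se)] <- 0
  }
  point <- pr$predictions
  clamp <- if (prevalence) function(x) pmin(1, pmax(0, x)) else identity
  z95 <- qnorm(0.975); z80 <- qnorm(0.90)
  out <- tibble(
    stratum_id = feat$stratum_id, month = feat$month,
    outcome = model$outcome %||% NA_character_, source = source,
    point = clamp(point), se = se,
    ci_low_95 = clamp(point - z95 * se), ci_high_95 = clamp(point + z95 * se),
    ci_low_80 = clamp(point - z80 * se), ci_high_80 = clamp(point + z80 * se))
  attr(out, "n_unpredicted") <- sum(!ok)
  out
}
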