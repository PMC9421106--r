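# Performance-evaluation suite: MSE, relative bias, relative precision,
# effective coverage and threshold sensitivity/specificity, plus the
# serialisable metrics report with predicted-vs-observed plot data.

#' Humanitarian decision thresholds for an outcome family
#'
#' The prevalence thresholds commonly used to trigger response: SAM 2% and
#' 5%, GAM 15% and 20%.
#'
#' @param family `"sam"` or `"gam"`.
#' @param lower,upper optional overrides in (0, 1).
#' @return a `nutcast_thresholds` object.
#' @export
threshold_set <- function(family = c("sam", "gam"), lower = NULL, upper = NULL) {
  family <- match.arg(family)
  defaults <- if (family == "sam") c(0.02, 0.05) else c(0.15, 0.20)
  lower <- lower %||% defaults[1]
  upper <- upper %||% defaults[2]
  if (!(lower < upper) || lower <= 0 || upper >= 1) {
    abort("need 0 < lower < upper < 1", class = "nutcast_domain_error")
  }
  structure(list(family = family, lower = lower, upper = upper),
            class = "nutcast_thresholds")
}

#' Match predictions to observed survey estimates
#'
#' Inner join of prediction records and observed stratum-month survey
#' estimates on (`stratum_id`, `month`) (and `outcome` where both carry
#' it).  Unmatched keys on either side are reported; zero matches is an
#' error.
#'
#' @param predictions prediction records (`stratum_id`, `month`, `point`,
#'   CI columns).
#' @param observed observed estimates (`stratum_id`, `month`, `point`, and
#'   the design-based CI columns `ci_low_95`, ... where available).
#' @return a tibble of pairs with prediction columns prefixed `pred_` and
#'   observation columns prefixed `obs_`; unmatched key counts in the
#'   `n_unmatched_pred` / `n_unmatched_obs` attributes.
#' @export
match_pairs <- function(predictions, observed) {
  predictions <- as_tibble(predictions)
  observed <- as_tibble(observed)
  keys <- c("stratum_id", "month",
            intersect("outcome", intersect(names(predictions), names(observed))))
  p <- rename_with(predictions, ~ paste0("pred_", .x),
                   .cols = -dplyr::all_of(keys))
  o <- rename_with(observed, ~ paste0("obs_", .x),
                   .cols = -dplyr::all_of(keys))
  pairs <- inner_join(p, o, by = keys, relationship = "many-to-many")
  if (nrow(pairs) == 0) {
    abort("no prediction-observation pairs share a key",
          class = "nutcast_evaluation_error")
  }
  attr(pairs, "n_unmatched_pred") <- nrow(dplyr::anti_join(p, o, by = keys))
  attr(pairs, "n_unmatched_obs") <- nrow(dplyr::anti_join(o, p, by = keys))
  pairs
}

#' Mean square error of matched pairs
#'
#' @param pairs a [match_pairs()] result.
#' @return mean of squared prediction errors.
#' @export
mse <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  mean((pairs$pred_point - pairs$obs_point)^2)
}

#' Relative bias of matched pairs
#'
#' The mean of `(prediction - observation) / observation` over pairs with a
#' non-zero observation; pairs with a zero observation are excluded from
#' the mean and counted.
#'
#' @param pairs a [match_pairs()] result.
#' @return a list with `value` (signed fraction, `NA` if every observation
#'   is zero) and `n_zero_obs`.
#' @export
relative_bias <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  nz <- pairs$obs_point != 0
  value <- if (!any(nz)) NA_real_ else
    mean((pairs$pred_point[nz] - pairs$obs_point[nz]) / pairs$obs_point[nz])
  list(value = value, n_zero_obs = sum(!nz))
}

#' Relative precision of predictions
#'
#' The mean ratio of the predicted one-sided 95% interval (half the CI
#' width) to the point estimate, over predictions with a non-zero point;
#' reported as a `+/- x` fraction.
#'
#' @param predictions prediction records with `point`, `ci_low_95`,
#'   `ci_high_95`.
#' @return a list with `value` and `n_zero_point`.
#' @export
relative_precision <- function(predictions) {
  stopifnot(nrow(predictions) >= 1)
  nz <- predictions$point != 0
  value <- if (!any(nz)) NA_real_ else
    mean(((predictions$ci_high_95[nz] - predictions$ci_low_95[nz]) / 2) /
           predictions$point[nz])
  list(value = value, n_zero_point = sum(!nz))
}

#' Effective coverage of predictions by observed survey CIs
#'
#' The fraction of pairs whose predicted point estimate falls inside the
#' observed survey's design-based confidence interval at the requested
#' level (closed interval).  Pairs lacking an observed CI are excluded and
#' counted.
#'
#' @param pairs a [match_pairs()] result carrying `obs_ci_low_95` etc.
#' @param level 0.95 or 0.80.
#' @return a list with `value` and `n_missing_ci`.
#' @export
effective_coverage <- function(pairs, level = 0.95) {
  stopifnot(level %in% c(0.95, 0.80), nrow(pairs) >= 1)
  suffix <- if (level == 0.95) "95" else "80"
  lo <- pairs[[paste0("obs_ci_low_", suffix)]]
  hi <- pairs[[paste0("obs_ci_high_", suffix)]]
  ok <- !is.na(lo) & !is.na(hi)
  value <- if (!any(ok)) NA_real_ else
    mean(pairs$pred_point[ok] >= lo[ok] & pairs$pred_point[ok] <= hi[ok])
  list(value = value, n_missing_ci = sum(!ok))
}

#' Sensitivity and specificity against prevalence thresholds
#'
#' At each threshold, the observed class is `observation >= threshold`
#' (gold standard) and the predicted class `prediction >= threshold`.
#' Sensitivity is the fraction of observed positives predicted positive,
#' specificity the fraction of observed negatives predicted negative;
#' each is `NA` when its denominator is zero.
#'
#' @param pairs a [match_pairs()] result.
#' @param thresholds a [threshold_set()].
#' @return a tibble with one row per threshold (`lower`, `upper`):
#'   `threshold`, `sensitivity`, `n_observed_positive`, `specificity`,
#'   `n_observed_negative`.
#' @export
threshold_classification <- function(pairs, thresholds) {
  stopifnot(inherits(thresholds, "nutcast_thresholds"), nrow(pairs) >= 1)
  purrr::map_dfr(c(lower = thresholds$lower, upper = thresholds$upper),
                 function(tau) {
    obs_pos <- pairs$obs_point >= tau
    pred_pos <- pairs$pred_point >= tau
    tibble(
      threshold = tau,
      sensitivity = if (any(obs_pos)) mean(pred_pos[obs_pos]) else NA_real_,
      n_observed_positive = sum(obs_pos),
      specificity = if (any(!obs_pos)) mean(!pred_pos[!obs_pos]) else NA_real_,
      n_observed_negative = sum(!obs_pos))
  }, .id = "which")
}

#' Assemble the full metrics report for one outcome
#'
#' Computes every performance metric per prediction source (train, loocv,
#' holdout) for one outcome, together with predicted-vs-observed plot data
#' carrying absolute-deviance band membership at 1, 2 and 3 percentage
#' points.
#'
#' @param predictions prediction records for one outcome, possibly several
#'   sources.
#' @param observed observed survey estimates for the same outcome with
#'   design-based 95% and 80% CIs.
#' @param thresholds a [threshold_set()], or `NULL` for continuous outcomes
#'   (classification is skipped).
#' @return a `nutcast_metrics_report`: list with `outcome`, `metrics`
#'   (tibble per source), `classification` (tibble per source x threshold,
#'   or `NULL`), `plot_data`.
#' @export
build_report <- function(predictions, observed, thresholds = NULL) {
  predictions <- as_tibble(predictions)
  outcome <- unique(predictions$outcome)
  stopifnot(length(outcome) == 1)
  sources <- unique(predictions$source)

  metrics <- purrr::map_dfr(sources, function(src) {
    preds <- filter(predictions, .data$source == src)
    pairs <- match_pairs(preds, observed)
    rb <- relative_bias(pairs)
    rp <- relative_precision(rename(pairs, point = "pred_point",
                                    ci_low_95 = "pred_ci_low_95",
                                    ci_high_95 = "pred_ci_high_95"))
    c95 <- effective_coverage(pairs, 0.95)
    c80 <- effective_coverage(pairs, 0.80)
    tibble(source = src, n = nrow(pairs), mse = mse(pairs),
           relative_bias = rb$value, n_zero_obs = rb$n_zero_obs,
           relative_precision = rp$value,
           coverage_95 = c95$value, coverage_80 = c80$value)
  })

  classification <- if (!is.null(thresholds)) {
    purrr::map_dfr(sources, function(src) {
      pairs <- match_pairs(filter(predictions, .data$source == src), observed)
      mutate(threshold_classification(pairs, thresholds), source = src,
             .before = 1)
    })
  } else NULL

  plot_data <- purrr::map_dfr(sources, function(src) {
    pairs <- match_pairs(filter(predictions, .data$source == src), observed)
    dev <- abs(pairs$pred_point - pairs$obs_point)
    tibble(source = src, stratum_id = pairs$stratum_id, month = pairs$month,
           observed = pairs$obs_point, predicted = pairs$pred_point,
           band = dplyr::case_when(dev <= 0.01 ~ "within_1pct",
                                   dev <= 0.02 ~ "within_2pct",
                                   dev <= 0.03 ~ "within_3pct",
                                   TRUE ~ "beyond_3pct"))
  })

  structure(list(outcome = outcome, metrics = metrics,
                 classification = classification, plot_data = plot_data),
            class = "nutcast_metrics_report")
}

#' @export
print.nutcast_metrics_report <- function(x, ...) {
  cat(sprintf("<nutcast_metrics_report> outcome %s\n", x$outcome))
  print(as.data.frame(x$metrics), digits = 4)
  invisible(x)
}

#' Write a metrics report to JSON and CSV
#'
#' Serialises the report losslessly: metrics and classification tables as
#' CSV, the whole report (including plot data) as a single JSON document.
#'
#' @param report a [build_report()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0("metrics_", report$outcome))
  paths <- paste0(stem, c(".json", "_metrics.csv", "_classification.csv",
                          "_plot_data.csv"))
  jsonlite::write_json(
    list(outcome = report$outcome, metrics = report$metrics,
         classification = report$classification, plot_data = report$plot_data),
    paths[1], digits = NA, na = "null", auto_unbox = TRUE)
  readr::write_csv(report$metrics, paths[2])
  if (!is.null(report$classification)) readr::write_csv(report$classification, paths[3])
  readr::write_csv(report$plot_data, paths[4])
  invisible(paths)
}

#' Read back a JSON metrics report
#'
#' @param path path to a JSON file written by [write_metrics_report()].
#' @return a `nutcast_metrics_report`.
#' @export
read_metrics_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(outcome = raw$outcome, metrics = as_tibble(raw$metrics),
                 classification = if (is.null(raw$classification)) NULL else
                   as_tibble(raw$classification),
                 plot_data = as_tibble(raw$plot_data)),
            class = "nutcast_metrics_report")
}
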