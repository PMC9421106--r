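# Predictor-panel engineering: missingness screening, imputation, rate
# conversion, smoothing, rolling means and lag-window features.

#' Screen predictors for excessive missingness
#'
#' A variable is excluded when the fraction of strata with no observed value
#' in one or more months reaches the threshold, or the fraction of months
#' with no observed value in one or more strata does.  Both fractions are
#' reported for every variable, kept or excluded.
#'
#' @param panel long-format panel (`stratum_id`, `month`, `variable`,
#'   `value`); `NA` values count as missing.
#' @param threshold exclusion threshold (default 0.30).
#' @return a list with `kept` (character vector), `excluded` (character
#'   vector) and `detail` (tibble: variable, `frac_strata_missing`,
#'   `frac_months_missing`, `excluded`).
#' @export
screen_missingness <- function(panel, threshold = 0.30) {
  panel <- as_tibble(panel)
  if (nrow(panel) == 0) abort("empty panel", class = "nutcast_domain_error")
  all_strata <- unique(panel$stratum_id)
  all_months <- unique(panel$month)
  detail <- panel |>
    group_by(.data$variable) |>
    summarise(
      frac_strata_missing =
        (length(all_strata) -
           dplyr::n_distinct(.data$stratum_id[!is.na(.data$value)])) /
        length(all_strata),
      frac_months_missing =
        (length(all_months) -
           dplyr::n_distinct(.data$month[!is.na(.data$value)])) /
        length(all_months),
      .groups = "drop") |>
    mutate(excluded = .data$frac_strata_missing >= threshold |
             .data$frac_months_missing >= threshold)
  list(kept = detail$variable[!detail$excluded],
       excluded = detail$variable[detail$excluded],
       detail = detail)
}

#' Linearly interpolate interior gaps in a monthly series
#'
#' Interior `NA` runs are filled by linear interpolation in time; leading
#' and trailing gaps are extended from the nearest observed value.  Filled
#' positions are reported so imputation provenance can be recorded.
#'
#' @param value numeric series ordered by month.
#' @param month optional month index (defaults to `seq_along(value)`).
#' @return a list with `value` (completed series) and `imputed` (logical).
#' @export
interpolate_series <- function(value, month = seq_along(value)) {
  obs <- !is.na(value)
  if (sum(obs) < 2) {
    abort("need at least 2 observed points to interpolate",
          class = "nutcast_domain_error")
  }
  filled <- approx(month[obs], value[obs], xout = month, rule = 2)$y
  list(value = ifelse(obs, value, filled), imputed = !obs)
}

#' Impute a market price series from neighbouring markets
#'
#' Missing cells receive `0.7 x nearest-market value + 0.3 x mean of all
#' other non-missing markets` for that month.  If the nearest market is also
#' missing, the mean of the non-missing markets is used (flagged); if every
#' market is missing that month, the cell is left `NA` for downstream
#' chained imputation.
#'
#' @param target numeric series for the market being completed.
#' @param nearest numeric series for the geographically nearest market.
#' @param others numeric matrix (months x markets) of all other markets.
#' @return a list with `value`, `imputed` (logical) and `fallback` (logical:
#'   nearest market was missing too).
#' @export
impute_market <- function(target, nearest, others) {
  others <- as.matrix(others)
  stopifnot(length(nearest) == length(target), nrow(others) == length(target))
  miss <- is.na(target)
  other_mean <- rowMeans(others, na.rm = TRUE)
  other_mean[is.nan(other_mean)] <- NA_real_
  value <- target
  fallback <- rep(FALSE, length(target))
  for (t in which(miss)) {
    if (!is.na(nearest[t]) && !is.na(other_mean[t])) {
      value[t] <- 0.7 * nearest[t] + 0.3 * other_mean[t]
    } else if (is.na(nearest[t]) && !is.na(other_mean[t])) {
      value[t] <- other_mean[t]
      fallback[t] <- TRUE
    } else if (!is.na(nearest[t]) && is.na(other_mean[t])) {
      value[t] <- nearest[t]
      fallback[t] <- TRUE
    }
  }
  list(value = value, imputed = miss & !is.na(value), fallback = fallback)
}

#' Chained-equations imputation of a wide panel
#'
#' Completes remaining missing cells by iterated stochastic regression:
#' missing values are initialised at the column means, then, cycling over
#' incomplete variables for `n_iterations` rounds, each variable is
#' regressed (normal linear model) on all other variables and its missing
#' cells replaced by draws from the fitted predictive distribution.  A
#' single completed dataset is returned, deterministic given the seed.
#' Zero-variance regressors are dropped from the relevant equation with a
#' warning.
#'
#' @param wide tibble keyed by (`stratum_id`, `month`) with one numeric
#'   column per variable.
#' @param n_iterations sweeps over the incomplete variables (default 10).
#' @param seed integer seed.
#' @return `wide` with missing cells filled, plus an `imputed_cells`
#'   attribute (logical matrix over the variable columns).
#' @export
impute_chained <- function(wide, n_iterations = 10, seed = 1L) {
  wide <- as_tibble(wide)
  key_cols <- intersect(c("stratum_id", "month"), names(wide))
  vars <- setdiff(names(wide), key_cols)
  X <- as.matrix(wide[, vars, drop = FALSE])
  miss <- is.na(X)
  if (!any(miss)) {
    attr(wide, "imputed_cells") <- miss
    return(wide)
  }
  incomplete <- vars[colSums(miss) > 0]
  for (v in incomplete) {
    frac_obs <- mean(!miss[, v])
    if (frac_obs < 0.30) {
      abort(sprintf("variable '%s' has under 30%% observed cells", v),
            class = "nutcast_domain_error")
    }
  }
  set.seed(seed)
  # mean initialisation
  for (v in vars) X[miss[, v], v] <- mean(X[, v], na.rm = TRUE)
  warned <- character()
  for (iter in seq_len(n_iterations)) {
    for (v in incomplete) {
      preds <- setdiff(vars, v)
      keep <- preds[apply(X[, preds, drop = FALSE], 2, sd) > 1e-12]
      if (length(keep) < length(preds) && !v %in% warned) {
        warn(sprintf("zero-variance regressors dropped from equation for '%s'", v))
        warned <- c(warned, v)
      }
      obs <- !miss[, v]
      if (length(keep) == 0) {
        mu <- mean(X[obs, v]); sig <- sd(X[obs, v])
        X[!obs, v] <- rnorm(sum(!obs), mu, max(sig, 1e-12))
        next
      }
      df <- as.data.frame(X[, c(v, keep), drop = FALSE])
      fit <- lm(as.formula(paste0("`", v, "` ~ .")), data = df[obs, , drop = FALSE])
      pred <- predict(fit, newdata = df[!obs, , drop = FALSE])
      sig <- summary(fit)$sigma
      if (!is.finite(sig)) sig <- 0
      X[!obs, v] <- pred + rnorm(sum(!obs), 0, sig)
    }
  }
  out <- wide
  out[, vars] <- as_tibble(as.data.frame(X))
  attr(out, "imputed_cells") <- miss
  out
}

#' Convert event counts to per-population rates
#'
#' @param count numeric count series.
#' @param population matching population series (> 0).
#' @param scale rate denominator (default per 100,000).
#' @return rate series; `NA` where the population is missing for an observed
#'   count.
#' @export
per_capita_rate <- function(count, population, scale = 1e5) {
  if (any(!is.na(population) & population <= 0)) {
    abort("populations must be positive", class = "nutcast_domain_error")
  }
  ifelse(is.na(population), NA_real_, count / population * scale)
}

#' Trailing three-month rolling mean
#'
#' Value at month t is the mean of the observed values in months t-2..t; the
#' first two months use the shorter available window.  Trailing (rather than
#' centred) windows avoid using future information in a now-casting setting.
#'
#' @param value numeric series ordered by month.
#' @param window window length in months (default 3).
#' @return smoothed series of the same length.
#' @export
rolling_mean <- function(value, window = 3) {
  n <- length(value)
  vapply(seq_len(n), function(t) {
    w <- value[max(1, t - window + 1):t]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Moderate cubic smoothing-spline fit of a monthly series
#'
#' Fits a cubic smoothing spline over time and returns its evaluation at
#' each month.  The default smoothing parameter `spar = 0.6` gives moderate
#' local smoothing; as the penalty grows the fit approaches the
#' least-squares line (which can be forced with a large `lambda`).  Series
#' with fewer than 4 observed points are returned unsmoothed with a
#' warning.
#'
#' @param value numeric series ordered by month.
#' @param month optional month index.
#' @param spar smoothing parameter in `[0, 1.5]` (default 0.6).
#' @param lambda optional direct penalty, overriding `spar`.
#' @return smoothed series evaluated at every month (observed or not, within
#'   the observed range).
#' @export
smooth_series <- function(value, month = seq_along(value), spar = 0.6,
                          lambda = NULL) {
  obs <- !is.na(value)
  if (sum(obs) < 4) {
    warn("fewer than 4 observed points: series returned unsmoothed")
    return(value)
  }
  fit <- if (is.null(lambda)) {
    smooth.spline(month[obs], value[obs], spar = spar)
  } else {
    smooth.spline(month[obs], value[obs], lambda = lambda)
  }
  out <- value
  inside <- month >= min(month[obs]) & month <= max(month[obs])
  out[inside] <- predict(fit, month[inside])$y
  out
}

#' Lag-window feature specification
#'
#' A feature is the mean of a variable over the window `start`..`end` months
#' prior to the reference month (e.g. `start = 2, end = 4` is the mean of
#' months t-4..t-2).  Climate variables are conventionally restricted to the
#' two trimesters (1-3, 4-6 prior) or the prior semester (1-6).
#'
#' @param variable variable name in the panel.
#' @param start,end window bounds in months prior (`1 <= start <= end`).
#' @return a `nutcast_lag_spec` object.
#' @export
lag_spec <- function(variable, start = 1, end = 3) {
  if (start < 1 || end < start) {
    abort("need 1 <= start <= end", class = "nutcast_domain_error")
  }
  structure(list(variable = variable, start = as.integer(start),
                 end = as.integer(end)),
            class = "nutcast_lag_spec")
}

lag_feature_name <- function(spec) {
  sprintf("%s_lag%d_%d", spec$variable, spec$start, spec$end)
}

#' Build the lag-window feature table
#'
#' For each reference stratum-month and each lag specification, computes the
#' mean of the variable over the window `end`..`start` months prior.  A
#' global `forecast_offset` shifts every window a further k months into the
#' past, turning a now-cast feature set into a k-month-ahead forecast set.
#' Static stratum covariates pass through unlagged.  Windows extending
#' before the start of the panel yield `NA` features.
#'
#' @param panel long-format completed panel (`stratum_id`, `month`,
#'   `variable`, `value`).
#' @param lag_specs list of [lag_spec()] objects.
#' @param reference tibble of reference stratum-months (`stratum_id`,
#'   `month`); default: every stratum-month in the panel.
#' @param forecast_offset non-negative uniform extra lag in months
#'   (default 0 = now-casting).
#' @param static optional tibble of static stratum covariates
#'   (`stratum_id` + columns), joined unlagged.
#' @return wide tibble keyed by (`stratum_id`, `month`) with one column per
#'   feature, named `<variable>_lag<start>_<end>`.
#' @export
build_features <- function(panel, lag_specs, reference = NULL,
                           forecast_offset = 0, static = NULL) {
  stopifnot(forecast_offset >= 0)
  panel <- as_tibble(panel)
  if (is.null(reference)) {
    reference <- distinct(panel, .data$stratum_id, .data$month)
  }
  out <- as_tibble(reference)
  for (spec in lag_specs) {
    sv <- filter(panel, .data$variable == spec$variable)
    lookup <- split(setNames(sv$value, sv$month), sv$stratum_id)
    lo <- spec$start + forecast_offset
    hi <- spec$end + forecast_offset
    out[[lag_feature_name(spec)]] <- purrr::map2_dbl(
      reference$stratum_id, reference$month,
      function(s, m) {
        ser <- lookup[[s]]
        if (is.null(ser)) return(NA_real_)
        months_wanted <- (m - hi):(m - lo)
        vals <- ser[as.character(months_wanted)]
        if (length(vals) < length(months_wanted) || anyNA(vals)) return(NA_real_)
        mean(vals)
      })
  }
  if (!is.null(static)) out <- left_join(out, as_tibble(static), by = "stratum_id")
  out
}
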