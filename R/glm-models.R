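# The GLM track: chronological split, per-predictor form/lag selection,
# all-subsets enumeration, weighted cluster-robust fitting, stratum-month
# prediction with simulated intervals, LOOCV and best-10% shortlisting.

GLM_OUTCOMES <- c("sam_wfh", "gam_wfh", "sam_muac", "gam_muac",
                  "mean_whz", "mean_muac")

outcome_family <- function(outcome) {
  if (outcome %in% c("mean_whz", "mean_muac")) "gaussian" else "quasibinomial"
}

#' Chronological train/holdout split of surveys
#'
#' Sorts surveys by month and assigns approximately the chronologically
#' first `train_fraction` to the training set and the most recent remainder
#' to the holdout set.  Surveys sharing the boundary month are kept together
#' in the training set, so the split never cuts through a month.
#'
#' @param meta survey metadata with a `month` column.
#' @param train_fraction fraction assigned to training (default 0.70).
#' @return a list with `train` and `holdout` tibbles (an error if either
#'   would be empty).
#' @export
chronological_split <- function(meta, train_fraction = 0.70) {
  meta <- as_tibble(meta)
  if (nrow(meta) < 2) abort("need at least 2 surveys", class = "nutcast_split_error")
  meta <- arrange(meta, .data$month, .data$survey_id)
  n_train <- ceiling(train_fraction * nrow(meta))
  boundary_month <- meta$month[n_train]
  in_train <- seq_len(nrow(meta)) <= n_train | meta$month == boundary_month
  if (all(in_train)) {
    abort("holdout set would be empty (all surveys fall in the training months)",
          class = "nutcast_split_error")
  }
  list(train = meta[in_train, ], holdout = meta[!in_train, ])
}

#' Aggregate child records into a cluster-level modelling frame
#'
#' Builds the data frame on which the GLMs are fitted: one row per survey
#' cluster, carrying the outcome value (case fraction for binary outcomes,
#' mean for continuous ones), the number of contributing children, the
#' analysis weight (children x survey weight, so the fit is exactly the
#' weighted child-level GLM), and the stratum-month feature columns.
#' Because features are constant within a survey, cluster-level aggregation
#' reproduces the child-level weighted fit exactly while keeping the
#' cluster structure needed for sandwich standard errors.
#'
#' @param children reanalysed child records (z-scores and exclusions set).
#' @param meta survey metadata with `analysis_weight`.
#' @param features wide feature table keyed by (`stratum_id`, `month`).
#' @param outcome one of `r paste(GLM_OUTCOMES, collapse = ", ")`.
#' @return a tibble with columns `survey_id`, `cluster`, `stratum_id`,
#'   `month`, `y`, `n_children`, `w` and the feature columns.
#' @export
build_model_frame <- function(children, meta, features, outcome) {
  outcome <- match.arg(outcome, GLM_OUTCOMES)
  meta <- as_tibble(meta)
  if (!"analysis_weight" %in% names(meta)) {
    meta$analysis_weight <- rescale_quality(meta$quality_score_raw) *
      meta$sampling_coverage
  }
  ch <- filter(as_tibble(children), .data$exclusion_reason == "none")
  yval <- switch(outcome,
    sam_wfh  = as.numeric(classify_children(ch, case_definition("wfh"))$status == "sam"),
    gam_wfh  = as.numeric(classify_children(ch, case_definition("wfh"))$gam),
    sam_muac = as.numeric(classify_children(ch, case_definition("muac"))$status == "sam"),
    gam_muac = as.numeric(classify_children(ch, case_definition("muac"))$gam),
    mean_whz = ch$whz,
    mean_muac = ch$muac_mm)
  ch$y <- yval
  ch <- filter(ch, !is.na(.data$y))
  frame <- ch |>
    group_by(.data$survey_id, .data$cluster_id) |>
    summarise(y = mean(.data$y), n_children = dplyr::n(), .groups = "drop") |>
    mutate(cluster = paste(.data$survey_id, .data$cluster_id, sep = ":")) |>
    left_join(select(meta, "survey_id", "stratum_id", "month", "analysis_weight"),
              by = "survey_id") |>
    mutate(w = .data$n_children * .data$analysis_weight) |>
    left_join(features, by = c("stratum_id", "month")) |>
    select(-"cluster_id", -"analysis_weight")
  attr(frame, "outcome") <- outcome
  frame
}

# Materialise the design columns implied by a list of predictor specs.
# Continuous specs pass the feature through; categorical specs cut it at
# fixed breakpoints (intervals closed on the left, reference = lowest).
spec_design <- function(data, specs) {
  out <- tibble(.rows = nrow(data))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    x <- data[[sp$column]]
    nm <- paste0("term_", i)
    if (sp$form == "categorical") {
      if (is.numeric(x)) {
        out[[nm]] <- cut(x, breaks = c(-Inf, sp$breaks, Inf), right = FALSE)
      } else {
        out[[nm]] <- factor(x, levels = sp$levels %||% sort(unique(x)))
      }
    } else {
      out[[nm]] <- x
    }
  }
  out
}

#' Select the best form and lag of one predictor
#'
#' Fits a univariate weighted GLM for each candidate version of a predictor
#' (continuous or categorical at given breakpoints, at each candidate lag
#' column) and tests it against the intercept-only model: a dispersion-scaled
#' Chi-square deviance test for quasi-binomial outcomes, an F test for
#' gaussian ones.  The candidate with the smallest p-value wins; exact ties
#' are broken towards the continuous form, then the shortest lag, then
#' candidate order.  Candidates whose fit fails (separation, zero variance)
#' are skipped; if all are skipped an error is raised.
#'
#' @param frame a [build_model_frame()] result.
#' @param candidates list of candidate specs, each a list with `column`
#'   (feature column name), `form` (`"continuous"` or `"categorical"`),
#'   optional `breaks` (increasing numeric), optional `levels` for factor
#'   predictors, and `lag_start` (for the tie-break).
#' @return the winning spec, with `p_value` attached, of class
#'   `nutcast_predictor_spec`.
#' @export
select_predictor_form <- function(frame, candidates) {
  outcome <- attr(frame, "outcome")
  fam <- outcome_family(outcome)
  results <- purrr::map(candidates, function(sp) {
    tryCatch({
      d <- bind_cols(frame[c("y", "w")], spec_design(frame, list(sp)))
      d <- d[complete.cases(d), ]
      if (nrow(d) < 3 || (is.factor(d$term_1) && dplyr::n_distinct(d$term_1) < 2) ||
          (is.numeric(d$term_1) && sd(d$term_1) < 1e-12)) return(NULL)
      family <- if (fam == "quasibinomial") quasibinomial() else gaussian()
      f1 <- suppressWarnings(glm(y ~ term_1, data = d, weights = d$w, family = family))
      f0 <- suppressWarnings(glm(y ~ 1, data = d, weights = d$w, family = family))
      if (!f1$converged) return(NULL)
      tst <- if (fam == "quasibinomial") {
        anova(f0, f1, test = "Chisq")
      } else {
        anova(f0, f1, test = "F")
      }
      p <- tst[2, ncol(tst)]
      if (is.na(p)) return(NULL)
      sp$p_value <- p
      sp
    }, error = function(e) NULL)
  })
  results <- purrr::compact(results)
  if (length(results) == 0) {
    abort("no candidate form could be estimated", class = "nutcast_selection_error")
  }
  ord <- order(
    vapply(results, function(r) r$p_value, numeric(1)),
    vapply(results, function(r) as.integer(r$form != "continuous"), integer(1)),
    vapply(results, function(r) r$lag_start %||% 0L, numeric(1))
  )
  best <- results[[ord[1]]]
  structure(best, class = "nutcast_predictor_spec")
}

#' Enumerate all-subsets candidate models
#'
#' Returns every non-empty subset of the selected predictor specs, up to
#' `max_terms` terms per model: sum over j of C(K, j) candidates.
#'
#' @param specs list of predictor specs.
#' @param max_terms maximum model size (default: all K).
#' @param max_candidates guard on the enumeration size (default 100000); an
#'   error asks to raise the cap or reduce K when exceeded.
#' @return a list of candidate skeletons, each a list of specs.
#' @export
enumerate_models <- function(specs, max_terms = length(specs),
                             max_candidates = 1e5) {
  if (length(specs) < 1) abort("need at least one predictor spec")
  k <- length(specs)
  max_terms <- min(max_terms, k)
  total <- sum(choose(k, seq_len(max_terms)))
  if (total > max_candidates) {
    abort(sprintf(
      "all-subsets enumeration would produce %d candidates (cap %d): raise max_candidates or reduce the number of predictors",
      total, max_candidates), class = "nutcast_enumeration_error")
  }
  out <- list()
  for (j in seq_len(max_terms)) {
    idx <- combn(k, j, simplify = FALSE)
    out <- c(out, lapply(idx, function(i) specs[i]))
  }
  out
}

#' Fit one weighted cluster-robust GLM candidate
#'
#' Fits the outcome on the candidate's design columns with the survey
#' analysis weights: quasi-binomial with logit link for binary outcomes,
#' gaussian for continuous ones.  The coefficient covariance is the sandwich
#' estimator clustered on survey x cluster.  Aliased (collinear) terms are
#' dropped with a warning; non-convergence flags the candidate.
#'
#' @param frame a [build_model_frame()] result (training rows).
#' @param specs list of predictor specs defining the candidate.
#' @return a `nutcast_glm` object: `fit`, `specs`, `outcome`, `family`,
#'   `coef`, `vcov` (robust), `dispersion`, `converged`.
#' @export
fit_glm <- function(frame, specs) {
  outcome <- attr(frame, "outcome")
  fam <- outcome_family(outcome)
  design <- spec_design(frame, specs)
  d <- bind_cols(frame[c("y", "w", "cluster")], design)
  d <- d[complete.cases(d), ]
  family <- if (fam == "quasibinomial") quasibinomial() else gaussian()
  rhs <- if (ncol(design) == 0) "1" else paste(names(design), collapse = " + ")
  fit <- suppressWarnings(
    glm(as.formula(paste("y ~", rhs)), data = d, weights = d$w, family = family))
  beta <- coef(fit)
  if (anyNA(beta)) {
    warn("collinear terms dropped from candidate model")
  }
  keep <- !is.na(beta)
  V <- sandwich::vcovCL(fit, cluster = d$cluster)
  dispersion <- summary(fit)$dispersion
  structure(list(fit = fit, specs = specs, outcome = outcome, family = fam,
                 coef = beta[keep], vcov = V, dispersion = dispersion,
                 converged = isTRUE(fit$converged), n_rows = nrow(d)),
            class = "nutcast_glm")
}

#' @export
print.nutcast_glm <- function(x, ...) {
  cat(sprintf("<nutcast_glm> outcome %s (%s), %d terms, %d rows%s\n",
              x$outcome, x$family, length(x$specs), x$n_rows,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict stratum-month outcomes with simulated intervals
#'
#' Evaluates a fitted candidate at target stratum-month feature rows.  The
#' point prediction is the fitted response (features are constant within a
#' stratum-month, so this equals the mean over that stratum-month's
#' children).  Intervals come from parametric simulation: coefficient draws
#' from a multivariate normal with the robust covariance, the response
#' recomputed per draw, and percentile 95% and 80% intervals taken.  When
#' `sampling_n` is supplied (the number of children a comparison survey
#' would measure), binomial sampling noise at that size is added to each
#' draw, giving a prediction interval for an *observed* survey estimate
#' rather than for the latent prevalence; for gaussian outcomes
#' `sampling_sd` plays the same role.
#'
#' @param model a [fit_glm()] result.
#' @param features target rows keyed by (`stratum_id`, `month`) carrying the
#'   model's feature columns.
#' @param n_draws simulation draws (default 10000).
#' @param seed integer seed making the interval deterministic.
#' @param sampling_n optional integer vector (recycled) of survey sizes for
#'   binary outcomes.
#' @param sampling_sd optional per-child sd for gaussian outcomes, used with
#'   `sampling_n` to add mean-sampling noise.
#' @param source label stored in the `source` column (default `"train"`).
#' @return a tibble of prediction records: `stratum_id`, `month`, `outcome`,
#'   `source`, `point`, `ci_low_95`, `ci_high_95`, `ci_low_80`, `ci_high_80`.
#'   Rows with missing features are dropped and reported via the
#'   `n_unpredicted` attribute.
#' @export
predict_stratum_month <- function(model, features, n_draws = 10000, seed = 1L,
                                  sampling_n = NULL, sampling_sd = NULL,
                                  source = "train") {
  features <- as_tibble(features)
  design <- spec_design(features, model$specs)
  ok <- complete.cases(design)
  n_missing <- sum(!ok)
  feat <- features[ok, ]
  design <- design[ok, , drop = FALSE]
  if (nrow(feat) == 0) {
    out <- tibble(stratum_id = character(), month = integer(),
                  outcome = character(), source = character(),
                  point = numeric(), ci_low_95 = numeric(),
                  ci_high_95 = numeric(), ci_low_80 = numeric(),
                  ci_high_80 = numeric())
    attr(out, "n_unpredicted") <- n_missing
    return(out)
  }
  terms_obj <- stats::delete.response(stats::terms(model$fit))
  X <- model.matrix(terms_obj, data = bind_cols(design),
                    xlev = model$fit$xlevels)
  X <- X[, names(model$coef), drop = FALSE]
  linkinv <- model$fit$family$linkinv
  eta <- as.numeric(X %*% model$coef)
  point <- linkinv(eta)

  set.seed(seed)
  V <- (model$vcov + t(model$vcov)) / 2
  draws <- MASS::mvrnorm(n_draws, mu = model$coef, Sigma = V)
  resp <- linkinv(X %*% t(draws))          # n_targets x n_draws
  if (!is.null(sampling_n)) {
    nvec <- rep(sampling_n, length.out = nrow(resp))
    if (model$family == "quasibinomial") {
      resp <- matrix(rbinom(length(resp), size = rep(nvec, ncol(resp)),
                            prob = pmin(1, pmax(0, resp))) /
                       rep(nvec, ncol(resp)),
                     nrow = nrow(resp))
    } else if (!is.null(sampling_sd)) {
      resp <- resp + matrix(rnorm(length(resp),
                                  sd = rep(sampling_sd / sqrt(nvec), ncol(resp))),
                            nrow = nrow(resp))
    }
  }
  qs <- unname(t(apply(resp, 1, quantile, probs = c(0.025, 0.975, 0.10, 0.90),
                       names = FALSE)))
  point <- unname(point)
  out <- tibble(
    stratum_id = feat$stratum_id, month = feat$month,
    outcome = model$outcome, source = source,
    point = point,
    ci_low_95 = pmin(qs[, 1], point), ci_high_95 = pmax(qs[, 2], point),
    ci_low_80 = pmin(qs[, 3], point), ci_high_80 = pmax(qs[, 4], point))
  attr(out, "n_unpredicted") <- n_missing
  out
}

#' Leave-one-survey-out cross-validation
#'
#' For each survey in the training frame, refits the candidate on all other
#' surveys' clusters and predicts the held-out survey's stratum-month.  The
#' unit of leave-out is one survey (one stratum-month); folds whose refit
#' fails are skipped and reported.
#'
#' @param frame a [build_model_frame()] result (training rows).
#' @param specs the candidate's predictor specs.
#' @param features feature table used to predict each held-out
#'   stratum-month.
#' @param n_draws,seed passed to [predict_stratum_month()].
#' @return a tibble of prediction records with `source = "loocv"` and a
#'   `survey_id` column; skipped folds are listed in the `skipped`
#'   attribute.
#' @export
loocv <- function(frame, specs, features, n_draws = 2000, seed = 1L) {
  surveys <- unique(frame$survey_id)
  if (length(surveys) < 3) abort("need at least 3 surveys for LOOCV")
  skipped <- character()
  preds <- purrr::map_dfr(seq_along(surveys), function(i) {
    sid <- surveys[i]
    fold <- frame[frame$survey_id != sid, ]
    attr(fold, "outcome") <- attr(frame, "outcome")
    target_key <- distinct(frame[frame$survey_id == sid, c("stratum_id", "month")])
    res <- tryCatch({
      m <- fit_glm(fold, specs)
      if (!m$converged) stop("no convergence")
      feat <- dplyr::semi_join(features, target_key, by = c("stratum_id", "month"))
      p <- predict_stratum_month(m, feat, n_draws = n_draws,
                                 seed = derive_seed(seed, i), source = "loocv")
      p$survey_id <- sid
      p
    }, error = function(e) NULL)
    if (is.null(res)) skipped <<- c(skipped, sid)
    res
  })
  attr(preds, "skipped") <- skipped
  preds
}

#' Shortlist candidates by holdout mean square error
#'
#' Computes each candidate's MSE between its stratum-month predictions and
#' the observed survey point estimates on the holdout set, sorts ascending,
#' and returns the best 10% (rounded up).  Ties are broken by fewer model
#' terms, then by the lexicographic order of the term columns.
#'
#' @param candidates list of fitted candidates, each a list with `model`
#'   (a `nutcast_glm`) and `holdout_pred` (prediction records).
#' @param observed holdout observations: tibble with `stratum_id`, `month`,
#'   `point` (and optionally `survey_id`).
#' @param fraction shortlist fraction (default 0.10).
#' @return the candidates ranked ascending by MSE, with `holdout_mse`
#'   attached, truncated to the shortlist size.
#' @export
shortlist_models <- function(candidates, observed, fraction = 0.10) {
  observed <- as_tibble(observed)
  scores <- purrr::map_dbl(candidates, function(cand) {
    prs <- inner_join(cand$holdout_pred,
                      select(observed, "stratum_id", "month", obs = "point"),
                      by = c("stratum_id", "month"))
    if (nrow(prs) == 0) return(NA_real_)
    mean((prs$point - prs$obs)^2)
  })
  if (all(is.na(scores))) {
    abort("no candidate has holdout overlap", class = "nutcast_shortlist_error")
  }
  nterms <- purrr::map_int(candidates, function(c) length(c$model$specs))
  lexkey <- purrr::map_chr(candidates, function(c)
    paste(sort(purrr::map_chr(c$model$specs, "column")), collapse = "|"))
  ord <- order(scores, nterms, lexkey, na.last = TRUE)
  keep <- head(ord, ceiling(fraction * length(candidates)))
  out <- candidates[keep]
  for (i in seq_along(out)) out[[i]]$holdout_mse <- scores[keep[i]]
  out
}
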