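# Reanalysis of raw child-level anthropometric survey records: exclusion
# flagging, SAM/GAM case definitions, quality/coverage weighting and
# design-based prevalence with cluster-robust uncertainty.

#' Rescale an ENA-style survey quality score
#'
#' ENA reports a composite quality score from 0% (best) to 50% (worst).
#' This maps it linearly onto `[0, 1]` with 1 = best:
#' `rescaled = 1 - 2 * raw`.
#'
#' @param quality_score_raw raw score(s) in `[0, 0.5]`.
#' @return rescaled score(s) in `[0, 1]`.
#' @export
#' @examples
#' rescale_quality(c(0, 0.125, 0.5))  # 1.00 0.75 0.00
rescale_quality <- function(quality_score_raw) {
  if (any(is.na(quality_score_raw)) ||
      any(quality_score_raw < 0 | quality_score_raw > 0.5)) {
    abort("raw quality score must lie in [0, 0.5]", class = "nutcast_domain_error")
  }
  1 - 2 * quality_score_raw
}

#' Approximate sampling coverage from accessible sampling units
#'
#' When a survey report states that some administrative level-3 units could
#' not be sampled (insecurity, inaccessibility), coverage is approximated as
#' the accessible fraction, e.g. 10 of 12 units gives 10/12.
#'
#' @param accessible_units number of units actually in the sampling frame.
#' @param total_units total number of units in the stratum.
#' @return the fraction `accessible_units / total_units`.
#' @export
sampling_coverage <- function(accessible_units, total_units) {
  if (any(total_units <= 0) || any(accessible_units <= 0) ||
      any(accessible_units > total_units)) {
    abort("need 0 < accessible_units <= total_units", class = "nutcast_domain_error")
  }
  accessible_units / total_units
}

#' Case definition for acute malnutrition
#'
#' Two alternative definitions are used in parallel: weight-for-height
#' (`"wfh"`: SAM below -3 z, GAM below -2 z) and MUAC (`"muac"`: SAM below
#' 115 mm, GAM below 125 mm).  Bilateral oedema always classifies a child as
#' SAM regardless of anthropometry.
#'
#' @param basis `"wfh"` or `"muac"`.
#' @param sam_cutoff,gam_cutoff optional overrides of the standard cutoffs.
#' @return a `nutcast_case_definition` object.
#' @export
case_definition <- function(basis = c("wfh", "muac"),
                            sam_cutoff = NULL, gam_cutoff = NULL) {
  basis <- match.arg(basis)
  defaults <- if (basis == "wfh") c(-3, -2) else c(115, 125)
  sam_cutoff <- sam_cutoff %||% defaults[1]
  gam_cutoff <- gam_cutoff %||% defaults[2]
  if (sam_cutoff >= gam_cutoff) {
    abort("SAM cutoff must be stricter (lower) than GAM cutoff",
          class = "nutcast_domain_error")
  }
  structure(list(basis = basis, sam_cutoff = sam_cutoff,
                 gam_cutoff = gam_cutoff, oedema_overrides = TRUE),
            class = "nutcast_case_definition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag records for exclusion
#'
#' Labels every record with exactly one `exclusion_reason`, applying the
#' rules in fixed order: (1) `missing` - no usable z-score and no MUAC and no
#' oedema; (2) `age_out_of_range` - age outside `age_range`; (3)
#' `flagged_outlier` - `|whz - center| > flag_limit`, where the centre is
#' either the reference median (0) or the survey's observed mean z-score per
#' the SMART convention.  Oedema-positive records are never excluded by the
#' outlier flag (their case status does not depend on the z-score).  MUAC
#' values are not subject to the z-flag; optional absolute plausibility
#' bounds can be enabled via `muac_bounds`.  Records are labelled, never
#' dropped.
#'
#' @param children tibble of child records with `whz` computed where
#'   computable (see [compute_whz()]).
#' @param flag_limit flag threshold in z-units (default 5).
#' @param age_range allowed age range in months (default `c(6, 59)`).
#' @param center `"survey_mean"` (default) or `"reference_zero"`.
#' @param muac_bounds optional length-2 numeric of absolute MUAC
#'   plausibility bounds in mm (e.g. `c(80, 220)`); `NULL` (default)
#'   disables them.
#' @return `children` with an `exclusion_reason` column
#'   (`"none"`, `"missing"`, `"age_out_of_range"`, `"flagged_outlier"`).
#' @export
apply_exclusions <- function(children, flag_limit = 5, age_range = c(6, 59),
                             center = c("survey_mean", "reference_zero"),
                             muac_bounds = NULL) {
  center <- match.arg(center)
  children <- as_tibble(children)
  if (!"whz" %in% names(children)) children$whz <- NA_real_
  if (!"muac_mm" %in% names(children)) children$muac_mm <- NA_real_
  oed <- !is.na(children$oedema) & children$oedema

  missing_rule <- is.na(children$age_months) |
    (is.na(children$whz) & is.na(children$muac_mm) & !oed)
  age_rule <- !missing_rule &
    (children$age_months < age_range[1] | children$age_months > age_range[2])

  ctr <- if (center == "reference_zero") {
    rep(0, nrow(children))
  } else {
    eligible <- !missing_rule & !age_rule & !is.na(children$whz)
    means <- tapply(children$whz[eligible], children$survey_id[eligible], mean)
    as.numeric(means[children$survey_id])
  }
  flag_rule <- !missing_rule & !age_rule & !oed & !is.na(children$whz) &
    !is.na(ctr) & abs(children$whz - ctr) > flag_limit
  if (!is.null(muac_bounds)) {
    flag_rule <- flag_rule | (!missing_rule & !age_rule & !oed &
      !is.na(children$muac_mm) &
      (children$muac_mm < muac_bounds[1] | children$muac_mm > muac_bounds[2]))
  }

  children$exclusion_reason <- dplyr::case_when(
    missing_rule ~ "missing",
    age_rule ~ "age_out_of_range",
    flag_rule ~ "flagged_outlier",
    TRUE ~ "none"
  )
  children
}

#' Classify children as SAM, MAM or neither
#'
#' Applies a [case_definition()]: bilateral oedema classifies as SAM
#' regardless of measurements; otherwise the basis measurement is compared
#' with the SAM and GAM cutoffs (strict `<` on the measurement).  A derived
#' `gam` logical marks SAM-or-MAM.  Excluded records and records whose basis
#' measurement is absent (without oedema) get `NA` status.
#'
#' @param children records carrying `exclusion_reason` (see
#'   [apply_exclusions()]).
#' @param definition a [case_definition()].
#' @return `children` with columns `status` (`"sam"`, `"mam"`, `"none"` or
#'   `NA`) and `gam` (logical).
#' @export
classify_children <- function(children, definition) {
  stopifnot(inherits(definition, "nutcast_case_definition"))
  children <- as_tibble(children)
  measure <- if (definition$basis == "wfh") children$whz else children$muac_mm
  oed <- !is.na(children$oedema) & children$oedema
  eligible <- children$exclusion_reason == "none"
  status <- rep(NA_character_, nrow(children))
  status[eligible & oed] <- "sam"
  anthro <- eligible & !oed & !is.na(measure)
  status[anthro & measure < definition$sam_cutoff] <- "sam"
  status[anthro & measure >= definition$sam_cutoff &
           measure < definition$gam_cutoff] <- "mam"
  status[anthro & measure >= definition$gam_cutoff] <- "none"
  children$status <- status
  children$gam <- ifelse(is.na(status), NA, status %in% c("sam", "mam"))
  children
}

#' Design-based prevalence (or mean) with cluster-robust uncertainty
#'
#' Estimates the survey-level outcome from non-excluded classified records:
#' the case fraction for binary outcomes (intercept-only binomial GLM) or the
#' mean for continuous outcomes (intercept-only gaussian fit), with the
#' variance clustered on `cluster_id` (sandwich estimator), matching a
#' design-based analysis of a cluster sample.  With a single cluster the
#' estimator falls back to the unclustered variance with a warning.
#' Confidence intervals are computed on the link scale and back-transformed.
#'
#' @param children classified records for one survey (see
#'   [classify_children()]); for `outcome = "continuous"` a `value` column is
#'   used instead of case status.
#' @param outcome `"sam"`, `"gam"` or `"continuous"`.
#' @param level confidence level(s); both 0.95 and 0.80 are returned by
#'   default.
#' @return one-row tibble: `n`, `point`, and `ci_low_95`, `ci_high_95`,
#'   `ci_low_80`, `ci_high_80` (for the levels requested).
#' @export
estimate_prevalence <- function(children, outcome = c("sam", "gam", "continuous"),
                                level = c(0.95, 0.80)) {
  outcome <- match.arg(outcome)
  kept <- filter(as_tibble(children), .data$exclusion_reason == "none")
  if (outcome != "continuous") kept <- filter(kept, !is.na(.data$status))
  if (nrow(kept) == 0) {
    abort("no non-excluded classified records", class = "nutcast_estimation_error")
  }
  y <- switch(outcome,
              sam = as.numeric(kept$status == "sam"),
              gam = as.numeric(kept$gam),
              continuous = kept$value)
  n <- length(y)
  single_cluster <- length(unique(kept$cluster_id)) < 2
  if (single_cluster) {
    warn("single cluster: falling back to unclustered variance")
  }

  if (outcome == "continuous") {
    fit <- lm(y ~ 1)
    point <- unname(coef(fit)[1])
    v <- if (single_cluster) sandwich::vcovHC(fit, type = "HC0")[1, 1] else
      sandwich::vcovCL(fit, cluster = kept$cluster_id)[1, 1]
    link <- point; se <- sqrt(v); back <- identity
  } else {
    point <- mean(y)
    if (point %in% c(0, 1)) {
      # degenerate: no variability on the link scale; report the point with
      # a Clopper-Pearson-style exact bound at each level
      out <- tibble(n = n, point = point)
      for (lv in level) {
        a <- 1 - lv
        lo <- if (point == 0) 0 else (a / 2)^(1 / n)
        hi <- if (point == 0) 1 - (a / 2)^(1 / n) else 1
        out[[sprintf("ci_low_%d", round(lv * 100))]] <- lo
        out[[sprintf("ci_high_%d", round(lv * 100))]] <- hi
      }
      return(out)
    }
    fit <- glm(y ~ 1, family = binomial())
    link <- unname(coef(fit)[1])
    v <- if (single_cluster) sandwich::vcovHC(fit, type = "HC0")[1, 1] else
      sandwich::vcovCL(fit, cluster = kept$cluster_id)[1, 1]
    se <- sqrt(v); back <- plogis
  }
  out <- tibble(n = n, point = if (outcome == "continuous") point else point)
  for (lv in level) {
    z <- qnorm(1 - (1 - lv) / 2)
    out[[sprintf("ci_low_%d", round(lv * 100))]] <- back(link - z * se)
    out[[sprintf("ci_high_%d", round(lv * 100))]] <- back(link + z * se)
  }
  out
}

#' Reanalyse a set of surveys end to end
#'
#' Runs the full reanalysis chain on raw child records: z-score computation
#' through the LMS reference, exclusion flagging, classification under both
#' case definitions, and design-based estimation of the six outcomes (SAM
#' and GAM under each definition, mean WHZ, mean MUAC) per survey, carrying
#' each survey's analysis weight.
#'
#' @param children raw child records (all surveys stacked).
#' @param meta survey metadata with `survey_id`, `stratum_id`, `month`,
#'   `quality_score_raw`, `sampling_coverage` (and optionally a precomputed
#'   `analysis_weight`).
#' @param reference LMS reference table.
#' @param flag_center passed to [apply_exclusions()].
#' @return a tibble with one row per survey x outcome: key columns, `n`,
#'   `point`, 95% and 80% CI bounds and `analysis_weight`.  The outcome
#'   labels are `sam_wfh`, `gam_wfh`, `sam_muac`, `gam_muac`, `mean_whz`,
#'   `mean_muac`.
#' @export
reanalyse_surveys <- function(children, meta, reference = synthetic_lms_table(),
                              flag_center = "survey_mean") {
  children <- compute_whz(children, reference)
  children <- apply_exclusions(children, center = flag_center)
  def_wfh <- case_definition("wfh")
  def_muac <- case_definition("muac")
  meta <- as_tibble(meta)
  if (!"analysis_weight" %in% names(meta)) {
    meta$analysis_weight <- rescale_quality(meta$quality_score_raw) *
      meta$sampling_coverage
  }

  purrr::map_dfr(meta$survey_id, function(sid) {
    ch <- filter(children, .data$survey_id == sid)
    m <- filter(meta, .data$survey_id == sid)
    ch_wfh <- classify_children(ch, def_wfh)
    ch_muac <- classify_children(ch, def_muac)
    rows <- list(
      sam_wfh  = estimate_prevalence(ch_wfh, "sam"),
      gam_wfh  = estimate_prevalence(ch_wfh, "gam"),
      sam_muac = estimate_prevalence(ch_muac, "sam"),
      gam_muac = estimate_prevalence(ch_muac, "gam"),
      mean_whz = estimate_prevalence(
        mutate(filter(ch, !is.na(.data$whz)), value = .data$whz), "continuous"),
      mean_muac = estimate_prevalence(
        mutate(filter(ch, !is.na(.data$muac_mm)), value = .data$muac_mm),
        "continuous")
    )
    bind_rows(rows, .id = "outcome") |>
      mutate(survey_id = sid, stratum_id = m$stratum_id, month = m$month,
             analysis_weight = m$analysis_weight, .before = 1)
  })
}
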