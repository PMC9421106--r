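#' Configuration for the synthetic-world generator
#'
#' Collects every tunable of the synthetic data-generating process in one
#' validated object.  The defaults describe a sparsely surveyed multi-stratum
#' crisis setting: monthly predictor series with strong autocorrelation,
#' block-wise missingness, SMART-style cluster surveys of children aged 6-59
#' months covering roughly a third of stratum-months, and prevalence levels
#' in the range reported for weight-for-height and MUAC case definitions in
#' East-African surveillance data.
#'
#' @param n_strata number of administrative strata (default 12).
#' @param n_months number of consecutive calendar months (default 30).
#' @param clusters_per_survey clusters sampled per survey (default 30).
#' @param children_per_cluster children measured per cluster (default 20).
#' @param icc target intra-cluster correlation of case status on the latent
#'   logistic scale, in `[0, 1)` (default 0.03).
#' @param missingness_block_rate target fraction of predictor cells removed
#'   in contiguous blocks, in `[0, 1)` (default 0.10).
#' @param predictor_ar lag-1 autocorrelation of the time-varying predictor
#'   series, in `[0, 1)` (default 0.7).
#' @param effect_sizes named numeric vector of logit-scale coefficients on
#'   the standardised 1-3-month lagged means of the named predictor-derived
#'   variables.
#' @param livelihood_effects named logit-scale offsets per livelihood type
#'   (reference: agriculturalist).
#' @param intercepts named logit-scale intercepts per binary outcome
#'   (`sam_wfh`, `gam_wfh`, `sam_muac`, `gam_muac`).
#' @param survey_fraction fraction of eligible stratum-months that receive a
#'   survey (default 0.30).
#' @param oedema_rate marginal probability of bilateral oedema (default 0.005).
#' @param missing_measure_rate fraction of children with a missing weight
#'   measurement (default 0.01).
#' @param age_out_rate fraction of children recorded with an age outside
#'   6-59 months (default 0.005).
#' @param lag_horizon months of predictor history required before the first
#'   surveyable month (default 6, the longest climate window).
#' @param seed integer seed governing all randomness.
#' @return an object of class `nutcast_config` (a validated list).
#' @export
generator_config <- function(n_strata = 12,
                             n_months = 30,
                             clusters_per_survey = 30,
                             children_per_cluster = 20,
                             icc = 0.03,
                             missingness_block_rate = 0.10,
                             predictor_ar = 0.7,
                             effect_sizes = c(conflict_deaths_rate = 0.25,
                                              measles_rate = 0.20,
                                              mean_ndvi = -0.25,
                                              water_price = 0.30),
                             livelihood_effects = c(agriculturalist = 0,
                                                    agropastoral = -0.10,
                                                    pastoralist = -0.30,
                                                    displaced = -0.20,
                                                    urban = -0.15),
                             intercepts = c(sam_wfh = qlogis(0.035),
                                            gam_wfh = qlogis(0.16),
                                            sam_muac = qlogis(0.012),
                                            gam_muac = qlogis(0.08)),
                             survey_fraction = 0.30,
                             oedema_rate = 0.005,
                             missing_measure_rate = 0.01,
                             age_out_rate = 0.005,
                             lag_horizon = 6,
                             seed = 1L) {
  cfg <- list(
    n_strata = as.integer(n_strata), n_months = as.integer(n_months),
    clusters_per_survey = as.integer(clusters_per_survey),
    children_per_cluster = as.integer(children_per_cluster),
    icc = icc, missingness_block_rate = missingness_block_rate,
    predictor_ar = predictor_ar, effect_sizes = effect_sizes,
    livelihood_effects = livelihood_effects, intercepts = intercepts,
    survey_fraction = survey_fraction, oedema_rate = oedema_rate,
    missing_measure_rate = missing_measure_rate, age_out_rate = age_out_rate,
    lag_horizon = as.integer(lag_horizon), seed = as.integer(seed)
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_strata < 1 || cfg$n_months < 1) {
    abort("n_strata and n_months must be positive", class = "nutcast_config_error")
  }
  if (cfg$clusters_per_survey < 1 || cfg$children_per_cluster < 1) {
    abort("clusters_per_survey and children_per_cluster must be >= 1",
          class = "nutcast_config_error")
  }
  for (nm in c("icc", "missingness_block_rate", "predictor_ar")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v >= 1) {
      abort(sprintf("%s must lie in [0, 1)", nm), class = "nutcast_config_error")
    }
  }
  for (nm in c("survey_fraction", "oedema_rate", "missing_measure_rate", "age_out_rate")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("%s must lie in [0, 1]", nm), class = "nutcast_config_error")
    }
  }
  need <- c("sam_wfh", "gam_wfh", "sam_muac", "gam_muac")
  if (!all(need %in% names(cfg$intercepts))) {
    abort("intercepts must name all four binary outcomes", class = "nutcast_config_error")
  }
  structure(cfg, class = "nutcast_config")
}

#' Read a generator configuration from a YAML file
#'
#' Scalar fields override the [generator_config()] defaults; named vectors
#' (`effect_sizes`, `livelihood_effects`, `intercepts`) are read as YAML
#' maps.
#'
#' @param path path to a YAML file.
#' @return a `nutcast_config` object.
#' @export
generator_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("effect_sizes", "livelihood_effects", "intercepts")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}
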