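test_that("quality rescaling maps the ENA scale onto [0,1] with best = 1", {
  expect_equal(rescale_quality(0), 1)
  expect_equal(rescale_quality(0.5), 0)
  expect_equal(rescale_quality(0.125), 0.75)
  expect_error(rescale_quality(0.6), class = "nutcast_domain_error")
  expect_error(rescale_quality(-0.1), class = "nutcast_domain_error")
})

test_that("sampling coverage is the accessible fraction of sampling units", {
  expect_equal(sampling_coverage(10, 12), 10 / 12)
  expect_equal(sampling_coverage(12, 12), 1)
  expect_equal(sampling_coverage(1, 4), 0.25)
  expect_error(sampling_coverage(5, 0), class = "nutcast_domain_error")
  expect_error(sampling_coverage(13, 12), class = "nutcast_domain_error")
})

test_that("case definitions apply the cutoffs with oedema override", {
  base <- tibble(survey_id = "s", cluster_id = 1, age_months = 24,
                 muac_mm = NA_real_, oedema = FALSE, whz = NA_real_,
                 exclusion_reason = "none")
  wfh <- case_definition("wfh"); muac <- case_definition("muac")

  ch <- dplyr::mutate(base, whz = -3.2)
  expect_equal(classify_children(ch, wfh)$status, "sam")
  ch <- dplyr::mutate(base, muac_mm = 114)
  expect_equal(classify_children(ch, muac)$status, "sam")
  ch <- dplyr::mutate(base, whz = -1.0, oedema = TRUE)
  expect_equal(classify_children(ch, wfh)$status, "sam")
  ch <- dplyr::mutate(base, whz = -2.5)
  out <- classify_children(ch, wfh)
  expect_equal(out$status, "mam"); expect_true(out$gam)

  expect_error(case_definition("wfh", sam_cutoff = -1, gam_cutoff = -2),
               class = "nutcast_domain_error")
})

test_that("exclusion rules label records in fixed order and never drop them", {
  ch <- tibble(survey_id = "s", cluster_id = 1,
               age_months = c(61, 24, 24, 24),
               muac_mm = c(120, NA, 130, 130),
               oedema = c(FALSE, FALSE, FALSE, TRUE),
               whz = c(-1, NA, -6, -6))
  # survey mean of eligible whz = mean(-1 is excluded by age... mean over
  # eligible records) — use reference centring for the arithmetic check
  out <- apply_exclusions(ch, center = "reference_zero")
  expect_equal(out$exclusion_reason,
               c("age_out_of_range", "missing", "flagged_outlier", "none"))
  expect_equal(nrow(out), 4)  # labelled, not dropped

  # survey-mean centring: observed mean ~ -0.7, so |-6 - mean| > 5 -> flagged
  ch2 <- tibble(survey_id = "s", cluster_id = 1, age_months = 24,
                muac_mm = NA, oedema = FALSE,
                whz = c(-6, rep(-0.5, 20)))
  out2 <- apply_exclusions(ch2, center = "survey_mean")
  expect_equal(out2$exclusion_reason[1], "flagged_outlier")
  expect_true(all(out2$exclusion_reason[-1] == "none"))

  # idempotence
  expect_equal(apply_exclusions(out, center = "reference_zero")$exclusion_reason,
               out$exclusion_reason)
})

test_that("exclusions match the brute-force three-rule filter on random records", {
  for (seed in c(7, 8)) {
    ch <- random_children(1000, seed)
    got <- apply_exclusions(ch, center = "reference_zero")$exclusion_reason
    expect_equal(got, bf_exclusions(ch, center = "reference_zero"))
  }
})

test_that("SAM is a subset of GAM on every random record set", {
  for (seed in 11:13) {
    ch <- apply_exclusions(random_children(400, seed), center = "reference_zero")
    for (basis in c("wfh", "muac")) {
      out <- classify_children(ch, case_definition(basis))
      expect_lte(sum(out$status == "sam", na.rm = TRUE),
                 sum(out$gam, na.rm = TRUE))
    }
  }
})

test_that("prevalence point estimate is the kept-record case fraction", {
  ch <- tibble(survey_id = "s", cluster_id = rep(1:2, 5), age_months = 24,
               muac_mm = NA, oedema = FALSE,
               whz = c(rep(-3.5, 2), rep(-1, 8)),
               exclusion_reason = "none")
  ch <- classify_children(ch, case_definition("wfh"))
  est <- estimate_prevalence(ch, "sam")
  expect_equal(est$point, 0.2)
  expect_equal(est$n, 10)
  expect_true(est$ci_low_95 <= 0.2 && est$ci_high_95 >= 0.2)
  expect_true(est$ci_low_80 >= est$ci_low_95)

  # invariant to cluster relabelling
  ch2 <- dplyr::mutate(ch, cluster_id = rev(cluster_id))
  expect_equal(estimate_prevalence(ch2, "sam")$point, est$point)

  # single cluster -> fallback with warning
  ch3 <- dplyr::mutate(ch, cluster_id = 1)
  expect_warning(estimate_prevalence(ch3, "sam"), "single cluster")

  expect_error(
    estimate_prevalence(dplyr::mutate(ch, exclusion_reason = "missing"), "sam"),
    class = "nutcast_estimation_error")
})

test_that("clustered CIs attain near-nominal coverage where naive CIs under-cover", {
  # strongly clustered binary outcome; 150 simulated surveys
  set.seed(42)
  reps <- 150; n_cl <- 20; n_ch <- 15
  p0 <- 0.2
  sig <- sqrt(nutcast:::icc_to_sigma2(0.2))
  delta <- nutcast:::logit_marginal_adjust(qlogis(p0), sig^2)
  hits_cl <- hits_naive <- 0
  for (r in seq_len(reps)) {
    u <- rnorm(n_cl, 0, sig)
    pcl <- plogis(qlogis(p0) + delta + u)
    y <- rbinom(n_cl * n_ch, 1, rep(pcl, each = n_ch))
    ch <- tibble(survey_id = "s", cluster_id = rep(1:n_cl, each = n_ch),
                 age_months = 24, muac_mm = NA, oedema = FALSE,
                 whz = ifelse(y == 1, -3.5, 0), exclusion_reason = "none")
    ch <- classify_children(ch, case_definition("wfh"))
    est <- estimate_prevalence(ch, "sam")
    if (p0 >= est$ci_low_95 && p0 <= est$ci_high_95) hits_cl <- hits_cl + 1
    # naive binomial Wald CI
    ph <- mean(y); se <- sqrt(ph * (1 - ph) / length(y))
    if (abs(ph - p0) <= qnorm(0.975) * se) hits_naive <- hits_naive + 1
  }
  band <- 3 * sqrt(0.95 * 0.05 / reps)
  expect_gt(hits_cl / reps, 0.95 - band)
  expect_lt(hits_naive / reps, hits_cl / reps)
  expect_lt(hits_naive / reps, 0.8)
})

test_that("reanalysis produces all six outcomes with weights as the product", {
  cfg <- tiny_config(seed = 9)
  w <- generate_world(cfg)
  sv <- generate_surveys(w, schedule = tibble(stratum_id = c("S01", "S02"),
                                              month = c(10, 12)))
  rea <- reanalyse_surveys(sv$children, sv$meta, w$lms)
  expect_setequal(unique(rea$outcome),
                  c("sam_wfh", "gam_wfh", "sam_muac", "gam_muac",
                    "mean_whz", "mean_muac"))
  expect_equal(nrow(rea), 12)
  expect_true(all(rea$analysis_weight >= 0 & rea$analysis_weight <= 1))
  m <- sv$meta
  expect_equal(m$analysis_weight, rescale_quality(m$quality_score_raw) *
                 m$sampling_coverage)
  # SAM <= GAM point estimates survey-wise
  wide <- tidyr::pivot_wider(rea[, c("survey_id", "outcome", "point")],
                             names_from = outcome, values_from = point)
  expect_true(all(wide$sam_wfh <= wide$gam_wfh))
  expect_true(all(wide$sam_muac <= wide$gam_muac))
})
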