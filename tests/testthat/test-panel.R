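make_panel <- function(n_strata, n_months, vars, seed = 1, miss_frac = 0) {
  set.seed(seed)
  p <- tidyr::crossing(stratum_id = sprintf("S%02d", 1:n_strata),
                       month = 1:n_months, variable = vars)
  p$value <- rnorm(nrow(p), 10, 3)
  if (miss_frac > 0) p$value[runif(nrow(p)) < miss_frac] <- NA
  p
}

test_that("missingness screening applies the 30% rule on both margins", {
  p <- make_panel(10, 12, c("a", "b"))
  # variable b absent in 5 of 10 strata
  p$value[p$variable == "b" & p$stratum_id %in% sprintf("S%02d", 1:5)] <- NA
  sc <- screen_missingness(p)
  expect_equal(sc$excluded, "b")
  expect_equal(sc$detail$frac_strata_missing[sc$detail$variable == "b"], 0.5)
  expect_equal(sc$kept, "a")
  expect_equal(sc$detail$frac_strata_missing[sc$detail$variable == "a"], 0)
  expect_equal(sc$detail$frac_months_missing[sc$detail$variable == "a"], 0)
})

test_that("screening equals brute-force margin fractions on random panels", {
  for (seed in 1:3) {
    p <- make_panel(6, 10, letters[1:4], seed = seed, miss_frac = 0.4)
    sc <- screen_missingness(p, 0.30)
    for (v in letters[1:4]) {
      pv <- p[p$variable == v, ]
      fs <- mean(vapply(unique(p$stratum_id), function(s)
        all(is.na(pv$value[pv$stratum_id == s])), logical(1)))
      fm <- mean(vapply(unique(p$month), function(m)
        all(is.na(pv$value[pv$month == m])), logical(1)))
      expect_equal(sc$detail$excluded[sc$detail$variable == v],
                   fs >= 0.30 || fm >= 0.30)
    }
    # threshold 0 excludes anything with a fully missing margin cell;
    # threshold > 1 excludes nothing
    expect_equal(length(screen_missingness(p, 1.01)$excluded), 0)
    sc0 <- screen_missingness(p, 0)
    expect_true(all(letters[1:4] %in% sc0$excluded))
  }
})

test_that("interpolation fills interior gaps linearly and extends the edges", {
  out <- interpolate_series(c(2, NA, 4))
  expect_equal(out$value, c(2, 3, 4))
  expect_equal(out$imputed, c(FALSE, TRUE, FALSE))

  full <- interpolate_series(c(1, 2, 3))
  expect_equal(full$value, c(1, 2, 3))
  expect_false(any(full$imputed))

  lead <- interpolate_series(c(NA, NA, 7, 9))
  expect_equal(lead$value, c(7, 7, 7, 9))

  expect_error(interpolate_series(c(NA, 5, NA)), class = "nutcast_domain_error")
})

test_that("market imputation uses the 0.7/0.3 weighted average with fallbacks", {
  out <- impute_market(c(NA, 5), nearest = c(10, 5),
                       others = matrix(c(25, 5, 15, 5), nrow = 2))
  expect_equal(out$value, c(0.7 * 10 + 0.3 * 20, 5))
  expect_equal(out$imputed, c(TRUE, FALSE))

  same <- impute_market(NA_real_, 5, matrix(5, 1, 2))
  expect_equal(same$value, 5)

  fb <- impute_market(NA_real_, NA_real_, matrix(c(4, 6), 1))
  expect_equal(fb$value, 5)
  expect_true(fb$fallback)

  none <- impute_market(NA_real_, NA_real_, matrix(NA_real_, 1, 2))
  expect_true(is.na(none$value))

  # brute-force oracle on random panels
  set.seed(5)
  for (r in 1:3) {
    tgt <- rnorm(24); tgt[sample(24, 8)] <- NA
    nr <- rnorm(24); nr[sample(24, 4)] <- NA
    oth <- matrix(rnorm(24 * 3), 24); oth[sample(length(oth), 20)] <- NA
    got <- impute_market(tgt, nr, oth)$value
    for (t in 1:24) {
      if (!is.na(tgt[t])) { expect_equal(got[t], tgt[t]); next }
      om <- mean(oth[t, ], na.rm = TRUE); om <- if (is.nan(om)) NA else om
      exp_v <- if (!is.na(nr[t]) && !is.na(om)) 0.7 * nr[t] + 0.3 * om
               else if (!is.na(om)) om else if (!is.na(nr[t])) nr[t] else NA_real_
      expect_equal(got[t], exp_v)
    }
  }
})

test_that("chained imputation is deterministic and recovers a linear system", {
  wide <- tibble(stratum_id = "S01", month = 1:20,
                 a = rnorm(20), b = rnorm(20))
  noop <- impute_chained(wide, seed = 1)
  attr(noop, "imputed_cells") <- NULL
  expect_identical(noop[, c("a", "b")], wide[, c("a", "b")])

  set.seed(77)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 + 1.5 * x1 - 0.8 * x2 + rnorm(n, 0, 0.3)
  full <- tibble(stratum_id = "S01", month = 1:n, x1 = x1, x2 = x2, y = y)
  holed <- full
  miss_idx <- sample(n, round(0.3 * n))
  holed$y[miss_idx] <- NA
  imp1 <- impute_chained(holed, seed = 42)
  imp2 <- impute_chained(holed, seed = 42)
  expect_identical(imp1, imp2)
  err <- imp1$y[miss_idx] - full$y[miss_idx]
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
  expect_lt(sqrt(mean(err^2)), sd(full$y))

  holed$x1[] <- 1  # zero-variance regressor
  expect_warning(impute_chained(holed, seed = 1), "zero-variance")
})

test_that("per-capita rates are counts scaled by population", {
  expect_equal(per_capita_rate(5, 5e4), 10)
  expect_equal(per_capita_rate(0, 1234), 0)
  expect_true(is.na(per_capita_rate(3, NA)))
  expect_error(per_capita_rate(3, 0), class = "nutcast_domain_error")
  set.seed(3)
  cnt <- rpois(50, 20); pop <- runif(50, 1e4, 2e5)
  expect_equal(per_capita_rate(cnt, pop), cnt / pop * 1e5)
})

test_that("trailing rolling means use shrinking edge windows", {
  expect_equal(rolling_mean(c(3, 6, 9)), c(3, 4.5, 6))
  expect_equal(rolling_mean(rep(4, 6)), rep(4, 6))
  set.seed(9)
  x <- rnorm(30); x[sample(30, 5)] <- NA
  got <- rolling_mean(x)
  exp_v <- vapply(1:30, function(t) {
    w <- x[max(1, t - 2):t]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  expect_equal(got, exp_v)
})

test_that("spline smoothing reproduces lines and shrinks towards least squares", {
  x <- 1:20; y <- 2 + 0.5 * x
  expect_equal(smooth_series(y), y, tolerance = 1e-8)

  set.seed(12)
  noisy <- 2 + 0.5 * x + rnorm(20, 0, 1)
  heavy <- smooth_series(noisy, lambda = 1e6)
  ols <- unname(predict(lm(noisy ~ x), newdata = data.frame(x = x)))
  expect_equal(heavy, ols, tolerance = 1e-3)

  sine <- sin(2 * pi * (1:36) / 12) + rnorm(36, 0, 0.8)
  smoothed <- smooth_series(sine)
  expect_lt(var(sine - smoothed), var(sine))

  expect_warning(out <- smooth_series(c(1, 2, 5)), "unsmoothed")
  expect_equal(out, c(1, 2, 5))
})

test_that("lag-window features are prior-window means with forecast offset", {
  p <- tibble(stratum_id = "S01", month = 1:12, variable = "v",
              value = c(0, 0, 3, 2, 1, 0, 0, 0, 0, 0, 0, 0))
  ref <- tibble(stratum_id = "S01", month = 7)
  f <- build_features(p, list(lag_spec("v", 2, 4)), ref)
  expect_equal(f$v_lag2_4, mean(c(3, 2, 1)))

  # forecast offset 3 on window 1-3 equals window 4-6 with offset 0
  ref2 <- tibble(stratum_id = "S01", month = 8:12)
  f13 <- build_features(p, list(lag_spec("v", 1, 3)), ref2, forecast_offset = 3)
  f46 <- build_features(p, list(lag_spec("v", 4, 6)), ref2)
  expect_equal(f13$v_lag1_3, f46$v_lag4_6)

  # window before panel start -> NA
  early <- build_features(p, list(lag_spec("v", 1, 3)), tibble(stratum_id = "S01", month = 2))
  expect_true(is.na(early$v_lag1_3))

  # static passthrough
  st <- tibble(stratum_id = "S01", livelihood = "urban")
  fs <- build_features(p, list(lag_spec("v", 1, 3)), ref, static = st)
  expect_equal(fs$livelihood, "urban")

  # brute-force oracle on random panels and specs
  set.seed(15)
  for (r in 1:3) {
    pp <- make_panel(3, 15, c("u", "w"), seed = 20 + r, miss_frac = 0.1)
    specs <- list(lag_spec("u", sample(1:2, 1), sample(3:5, 1)),
                  lag_spec("w", 1, sample(2:4, 1)))
    refr <- tidyr::crossing(stratum_id = sprintf("S%02d", 1:3), month = 6:15)
    got <- build_features(pp, specs, refr)
    for (spec in specs) {
      cn <- sprintf("%s_lag%d_%d", spec$variable, spec$start, spec$end)
      for (i in seq_len(nrow(refr))) {
        vals <- vapply((refr$month[i] - spec$end):(refr$month[i] - spec$start),
                       function(m) {
          v <- pp$value[pp$stratum_id == refr$stratum_id[i] & pp$month == m &
                          pp$variable == spec$variable]
          if (length(v) == 0) NA_real_ else v
        }, numeric(1))
        exp_v <- if (anyNA(vals)) NA_real_ else mean(vals)
        expect_equal(got[[cn]][i], exp_v)
      }
    }
  }
})
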