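# Helper: a survey-level modelling frame simulated from a known logistic
# surface (one aggregated row per survey; the exact frame fit_glm consumes).
sim_frame <- function(n_surveys, beta, intercept = qlogis(0.15), n_child = 500,
                      seed = 1, outcome = "gam_wfh", n_strata = 8) {
  set.seed(seed)
  k <- length(beta)
  grid <- tidyr::crossing(stratum_id = sprintf("S%02d", 1:n_strata), month = 1:24)
  sm <- grid[sample(nrow(grid), n_surveys), ]
  X <- matrix(rnorm(n_surveys * k), n_surveys, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  p <- plogis(intercept + as.numeric(X %*% beta))
  frame <- tibble(survey_id = paste0("sv", seq_len(n_surveys)),
                  cluster = paste0("sv", seq_len(n_surveys)),
                  stratum_id = sm$stratum_id, month = sm$month,
                  y = rbinom(n_surveys, n_child, p) / n_child,
                  n_children = n_child, w = n_child)
  frame <- dplyr::bind_cols(frame, tibble::as_tibble(X))
  attr(frame, "outcome") <- outcome
  frame
}

cont_specs <- function(cols) lapply(cols, function(v) list(column = v, form = "continuous"))

test_that("chronological split is a whole-month 70/30 partition", {
  meta <- tibble(survey_id = paste0("sv", 1:10), month = 1:10)
  sp <- chronological_split(meta)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$holdout), 3)
  expect_true(max(sp$train$month) < min(sp$holdout$month))

  same <- tibble(survey_id = paste0("sv", 1:5), month = 3)
  expect_error(chronological_split(same), class = "nutcast_split_error")
  expect_error(chronological_split(meta[1, ]), class = "nutcast_split_error")

  set.seed(2)
  for (r in 1:5) {
    m <- tibble(survey_id = paste0("sv", 1:40),
                month = sample(1:12, 40, replace = TRUE))
    sp <- chronological_split(m)
    expect_setequal(c(sp$train$survey_id, sp$holdout$survey_id), m$survey_id)
    expect_length(intersect(sp$train$survey_id, sp$holdout$survey_id), 0)
    # the boundary month is never split across the two sets
    expect_length(intersect(sp$train$month, sp$holdout$month), 0)
  }
})

test_that("form selection favours the generating predictor over noise", {
  frame <- sim_frame(120, beta = c(x1 = 0.6, x2 = 0), seed = 3)
  cands <- list(list(column = "x1", form = "continuous", lag_start = 1),
                list(column = "x2", form = "continuous", lag_start = 1))
  p1 <- select_predictor_form(frame, cands[1])$p_value
  p2 <- select_predictor_form(frame, cands[2])$p_value
  expect_lt(p1, p2)
  best <- select_predictor_form(frame, cands)
  expect_equal(best$column, "x1")

  single <- select_predictor_form(frame, cands[2])
  expect_equal(single$column, "x2")
})

test_that("selection p-values are uniform under the null (gaussian F test)", {
  # continuous outcome, pure-noise predictor: F-test p-values are exactly
  # uniform; checked over 500 replicates with a KS test at alpha = 0.01
  set.seed(8)
  pvals <- vapply(1:500, function(r) {
    n <- 40
    frame <- tibble(survey_id = paste0("sv", 1:n), cluster = paste0("sv", 1:n),
                    stratum_id = "S01", month = 1:n,
                    y = rnorm(n), n_children = 1, w = 1, x = rnorm(n))
    attr(frame, "outcome") <- "mean_whz"
    select_predictor_form(frame, cont_specs("x"))$p_value
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("all-subsets enumeration counts and uniqueness are correct", {
  specs <- cont_specs(c("a", "b", "c", "d"))
  expect_length(enumerate_models(specs[1:3]), 7)
  expect_length(enumerate_models(specs, max_terms = 2), 10)
  subsets <- enumerate_models(specs)
  keys <- vapply(subsets, function(s)
    paste(sort(vapply(s, function(x) x$column, character(1))), collapse = "|"),
    character(1))
  expect_length(subsets, 15)
  expect_false(any(duplicated(keys)))
  # brute-force subset completeness
  all_bf <- unlist(lapply(1:4, function(j)
    apply(combn(c("a", "b", "c", "d"), j), 2, paste, collapse = "|")))
  expect_setequal(keys, all_bf)
  expect_error(enumerate_models(specs, max_candidates = 3),
               class = "nutcast_enumeration_error")
})

test_that("weighted fits are invariant to constant and split weights", {
  frame <- sim_frame(80, beta = c(x1 = 0.5), seed = 5)
  specs <- cont_specs("x1")
  m1 <- fit_glm(frame, specs)

  # all weights equal (up to a constant) -> identical point estimates
  f2 <- frame; f2$w <- f2$w / 500
  attr(f2, "outcome") <- "gam_wfh"
  m2 <- fit_glm(f2, specs)
  expect_equal(m1$coef, m2$coef, tolerance = 1e-8)

  # duplicating every row at half weight -> identical coefficients
  f3 <- dplyr::bind_rows(frame, frame)
  f3$w <- f3$w / 2
  attr(f3, "outcome") <- "gam_wfh"
  m3 <- fit_glm(f3, specs)
  expect_equal(m1$coef, m3$coef, tolerance = 1e-8)

  # collinear term dropped with warning
  f4 <- frame; f4$x1b <- f4$x1
  attr(f4, "outcome") <- "gam_wfh"
  expect_warning(m4 <- fit_glm(f4, cont_specs(c("x1", "x1b"))), "collinear")
  expect_equal(unname(m4$coef[2]), unname(m1$coef[2]), tolerance = 1e-8)
})

test_that("stratum-month predictions honour the link and interval limits", {
  frame <- sim_frame(60, beta = c(x1 = 0), intercept = qlogis(0.2), seed = 6)
  m <- fit_glm(frame, list())          # intercept-only
  feats <- tibble(stratum_id = "S01", month = 1:5)
  pr <- predict_stratum_month(m, feats, n_draws = 500, seed = 1)
  expect_equal(pr$point, rep(plogis(m$coef[[1]]), 5))
  expect_true(all(pr$ci_low_95 <= pr$point & pr$point <= pr$ci_high_95))
  expect_true(all(pr$point >= 0 & pr$point <= 1))

  # zero covariance -> degenerate interval at the point
  m0 <- m; m0$vcov <- matrix(0, 1, 1, dimnames = list(names(m$coef), names(m$coef)))
  pr0 <- predict_stratum_month(m0, feats, n_draws = 200, seed = 1)
  expect_equal(pr0$ci_low_95, pr0$point)
  expect_equal(pr0$ci_high_95, pr0$point)

  # gaussian intercept-only: percentile CI matches the closed form
  set.seed(7)
  gf <- tibble(survey_id = paste0("sv", 1:200), cluster = paste0("sv", 1:200),
               stratum_id = "S01", month = rep(1:20, 10),
               y = rnorm(200, 0.5, 0.2), n_children = 1, w = 1)
  attr(gf, "outcome") <- "mean_whz"
  gm <- fit_glm(gf, list())
  gpr <- predict_stratum_month(gm, tibble(stratum_id = "S01", month = 1),
                               n_draws = 10000, seed = 2)
  se <- sqrt(gm$vcov[1, 1])
  expect_equal(gpr$ci_low_95, gm$coef[[1]] - qnorm(0.975) * se, tolerance = 5e-3)
  expect_equal(gpr$ci_high_95, gm$coef[[1]] + qnorm(0.975) * se, tolerance = 5e-3)
})

test_that("LOOCV leaves out exactly one survey and never peeks at it", {
  frame <- sim_frame(15, beta = c(x1 = 0.4), seed = 9)
  feats <- dplyr::distinct(frame, stratum_id, month, x1)
  cv <- loocv(frame, cont_specs("x1"), feats, n_draws = 100, seed = 1)
  expect_lte(nrow(cv), 15)
  expect_setequal(unique(cv$source), "loocv")

  # grossly corrupting one survey's outcome leaves its own fold unchanged
  k <- frame$survey_id[3]
  f2 <- frame; f2$y[f2$survey_id == k] <- 0.999
  attr(f2, "outcome") <- "gam_wfh"
  cv2 <- loocv(f2, cont_specs("x1"), feats, n_draws = 100, seed = 1)
  expect_equal(cv$point[cv$survey_id == k], cv2$point[cv2$survey_id == k])
  # ... while other folds (which train on the corrupted survey) move
  expect_false(isTRUE(all.equal(cv$point[cv$survey_id != k],
                                cv2$point[cv2$survey_id != k])))
})

test_that("shortlisting reproduces the brute-force MSE ranking", {
  set.seed(11)
  obs <- tibble(stratum_id = sprintf("S%02d", 1:12), month = 1:12,
                point = runif(12, 0.05, 0.3))
  fake_cand <- function(noise, nterms) {
    pred <- tibble(stratum_id = obs$stratum_id, month = obs$month,
                   point = obs$point + rnorm(12, 0, noise))
    list(model = structure(list(specs = cont_specs(letters[seq_len(nterms)])),
                           class = "nutcast_glm"),
         holdout_pred = pred)
  }
  cands <- lapply(runif(40, 0, 0.2), function(s) fake_cand(s, sample(1:4, 1)))
  short <- shortlist_models(cands, obs)
  expect_length(short, 4)  # ceiling(0.1 * 40)

  bf <- vapply(cands, function(c)
    mean((c$holdout_pred$point - obs$point)^2), numeric(1))
  expect_equal(vapply(short, function(s) s$holdout_mse, numeric(1)),
               sort(bf)[1:4])

  # a perfect candidate always ranks first
  perfect <- fake_cand(0, 2)
  short2 <- shortlist_models(c(cands, list(perfect)), obs)
  expect_equal(short2[[1]]$holdout_mse, 0)

  expect_error(
    shortlist_models(cands, dplyr::mutate(obs, stratum_id = "ZZ")),
    class = "nutcast_shortlist_error")
})
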