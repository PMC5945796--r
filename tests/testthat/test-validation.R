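test_that("fit_linear matches the normal-equation oracle", {
  perfect <- fit_linear(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$see, 0)

  x <- c(1, 2, 3)
  y <- c(2, 4, 7)
  fit <- fit_linear(x, y)
  oracle <- ols_oracle(x, y)
  expect_equal(fit$slope, oracle$slope)
  expect_equal(fit$intercept, oracle$intercept)
  expect_equal(fit$see, oracle$see) # = sqrt(1/6) here
  expect_equal(fit$see, sqrt(1 / 6), tolerance = 1e-12)

  withr::with_seed(8, {
    x <- rnorm(50)
    y <- 2 * x + rnorm(50)
    fit <- fit_linear(x, y)
    oracle <- ols_oracle(x, y)
    expect_equal(fit$see, oracle$see)
  })

  expect_error(fit_linear(c(1, 2), c(1, 2)), class = "hipscreen_data_error")
  expect_error(fit_linear(c(2, 2, 2), c(1, 2, 3)), class = "hipscreen_data_error")
})

test_that("normalised regression error behaves and scales correctly", {
  expect_equal(normalised_see(list(see = 0), 100), 0)
  expect_equal(normalised_see(list(see = 506), 3265), 100 * 506 / 3265) # ~15.5
  expect_equal(normalised_see(list(see = 718), 3265), 100 * 718 / 3265) # ~22.0
  expect_error(normalised_see(list(see = 1), 0), class = "hipscreen_domain_error")

  # invariance under common rescaling of both variables
  withr::with_seed(21, {
    x <- runif(30, 1, 5)
    y <- 3 * x + rnorm(30)
    a <- normalised_see(fit_linear(x, y), mean(y))
    b <- normalised_see(fit_linear(7 * x, 7 * y), mean(7 * y))
    expect_equal(a, b)
  })
})

test_that("rank AUC equals the Mann-Whitney pair count with midrank ties", {
  expect_equal(rank_auc(c(1, 2), c(3, 4)), 1)
  expect_equal(rank_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(rank_auc(c(1, 3), c(2, 4)), 0.75)

  withr::with_seed(33, {
    for (i in 1:20) {
      cases <- sample(1:8, 11, replace = TRUE)      # heavy ties
      controls <- sample(3:10, 7, replace = TRUE)
      expect_equal(rank_auc(cases, controls), brute_auc(cases, controls))
      # complement identity (midrank ties keep the two orientations summing to 1)
      expect_equal(rank_auc(cases, controls) + rank_auc(controls, cases), 1)
      # invariance under a strictly increasing transform
      expect_equal(rank_auc(exp(cases / 2), exp(controls / 2)),
                   rank_auc(cases, controls))
    }
  })
  expect_error(rank_auc(numeric(), 1), class = "hipscreen_data_error")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    cases <- rnorm(80, 2500, 700)
    controls <- rnorm(90, 3400, 700)
    ours <- rank_auc(cases, controls)
    ref <- pROC::auc(
      response = c(rep(1, 80), rep(0, 90)),
      predictor = c(cases, controls),
      direction = ">", quiet = TRUE # low score indicates the event
    )
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("threshold classification enumerates the confusion matrix", {
  perfect <- tibble::tibble(
    subject_id = letters[1:4],
    group = c("fracture", "fracture", "control", "control"),
    t_score = c(-3.5, -3.0, -1.0, 0.5)
  )
  rep <- classify(perfect, threshold_rule("t_score", -2.5))
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$accuracy, 1)

  # boundary subject (control at exactly -2.5) classifies positive
  mixed <- tibble::tibble(
    subject_id = letters[1:4],
    group = c("fracture", "fracture", "control", "control"),
    t_score = c(-3.0, -2.0, -2.5, -1.0)
  )
  rep <- classify(mixed, threshold_rule("t_score", -2.5))
  expect_equal(rep$sensitivity, 0.5)
  expect_equal(rep$specificity, 0.5)
  expect_equal(rep$accuracy, 0.5)

  # extreme cutoffs under at-or-below-positive
  lo <- classify(mixed, threshold_rule("t_score", -Inf))
  expect_equal(c(lo$sensitivity, lo$specificity), c(0, 1))
  hi <- classify(mixed, threshold_rule("t_score", Inf))
  expect_equal(c(hi$sensitivity, hi$specificity), c(1, 0))

  # missing rule variable names the offending subjects
  broken <- mixed
  broken$t_score[2] <- NA
  expect_error(classify(broken, threshold_rule("t_score", -2.5)), "b",
               class = "hipscreen_data_error")
})

test_that("classification accuracy matches the analytic binormal value", {
  spec <- cohort_spec(n_pairs = 5000, random_seed = 77)
  co <- generate_cohort(spec)
  cutoff <- 2551
  rep <- classify(co, threshold_rule("mss_newtons", cutoff))
  score_sd <- sqrt(spec$strength_sd_fracture^2 +
                     (spec$see_fraction * spec$mean_strength)^2)
  sens <- pnorm(cutoff, spec$strength_mean_fracture, score_sd)
  spc <- 1 - pnorm(cutoff, spec$strength_mean_control, score_sd)
  expect_lt(abs(rep$accuracy - (sens + spc) / 2), 0.02)
})

test_that("body-weight conversions invert each other", {
  expect_equal(strength_to_bw_multiple(3000, 80.7, 9.81), 3000 / (80.7 * 9.81))
  expect_equal(round(strength_to_bw_multiple(3000, 80.7), 1), 3.8) # "~four body weights"
  expect_equal(bw_multiple_to_strength(4, 65, 9.81), 2550.6)
  expect_equal(strength_to_bw_multiple(0, 70), 0)
  expect_equal(
    bw_multiple_to_strength(strength_to_bw_multiple(2870, 63.2), 63.2), 2870)
  expect_error(strength_to_bw_multiple(3000, 0), class = "hipscreen_domain_error")
})

test_that("zero-noise cohorts give zero %SEE and identical predictor AUCs", {
  co <- generate_cohort(cohort_spec(
    n_pairs = 300, see_fraction = 0, ser_fraction = 0.22,
    strength_mean_control = 3800, strength_mean_fracture = 2700,
    strength_sd_control = 800, strength_sd_fracture = 800, random_seed = 6
  ))
  acc <- cohort_accuracy(co)
  expect_equal(acc$pct_see, 0, tolerance = 1e-10)
  is_case <- co$group == "fracture"
  expect_identical(
    rank_auc(co$predicted_mss_n[is_case], co$predicted_mss_n[!is_case]),
    rank_auc(co$measured_strength_n[is_case], co$measured_strength_n[!is_case]))
})

test_that("accuracy summary degrades gracefully without measured strength", {
  co <- generate_cohort(cohort_spec(n_pairs = 50, random_seed = 3))
  co$measured_strength_n <- NA_real_
  expect_warning(acc <- cohort_accuracy(co), "SEE")
  expect_true(is.na(acc$pct_see) && is.na(acc$pct_ser))
  expect_false(is.na(acc$auc_mss))
})
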